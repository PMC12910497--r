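# Study-level statistics: control normalisation, two-way fixed-effects
# ANOVA (membrane x concentration) and Tukey HSD post hoc comparisons.

#' Normalise per-condition values to their control
#'
#' Divides every value by the mean of its membrane's control
#' (`conc == 0`) group, so controls map to 1. Following the study
#' convention, the control's dispersion is reported as the relative SD of
#' the raw control measurements prior to normalisation, which is identical
#' to the SD of the normalised control replicates.
#'
#' @param tbl Tidy measurement table: columns `membrane`, `conc`, `value`
#'   (extra columns pass through).
#' @return The input with `rel_value` added (`value / control mean`).
#' @examples
#' normalize_to_control(data.frame(membrane = "DOPC", conc = c(0, 40),
#'                                 value = c(73, 83)))
#' @export
normalize_to_control <- function(tbl) {
  stopifnot(is.data.frame(tbl),
            all(c("membrane", "conc", "value") %in% names(tbl)))
  out <- tbl |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$membrane) |>
    dplyr::mutate(.ctrl = mean(.data$value[.data$conc == 0])) |>
    dplyr::ungroup()
  if (any(!is.finite(out$.ctrl)) || any(out$.ctrl == 0)) {
    abort("Every membrane needs a nonzero control (conc == 0) mean.",
          class = "memphys_missing_control")
  }
  out |>
    dplyr::mutate(rel_value = .data$value / .data$.ctrl) |>
    dplyr::select(-".ctrl")
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Partitions the sums of squares of `value` into membrane, concentration,
#' interaction and residual terms (`stats::aov`, the standard balanced
#' fixed-effects decomposition) with F tests. Unbalanced designs fall back
#' to a Type-II decomposition (`car::Anova`) with a warning.
#'
#' @param tbl Tidy table: `membrane`, `conc`, `replicate`, `value`; factors
#'   are coerced. Every cell needs at least 2 replicates.
#' @return A `memphys_anova` object: `tidy()` gives the ANOVA table
#'   (`term`, `df`, `sumsq`, `meansq`, `statistic`, `p.value`), `glance()`
#'   the residual df and mean square. The fitted `aov` object is kept in
#'   `$fit` for post hoc use.
#' @examples
#' tbl <- gen_study_dataset(n_replicates = 3, seed = 1) |>
#'   dplyr::filter(observable == "pf")
#' tidy(two_way_anova(tbl))
#' @export
two_way_anova <- function(tbl) {
  stopifnot(is.data.frame(tbl),
            all(c("membrane", "conc", "value") %in% names(tbl)))
  d <- data.frame(membrane = factor(tbl$membrane), conc = factor(tbl$conc),
                  value = tbl$value)
  cells <- table(d$membrane, d$conc)
  if (any(cells < 2)) {
    abort("Every (membrane, conc) cell needs >= 2 replicates.",
          class = "memphys_bad_design")
  }
  balanced <- length(unique(as.vector(cells))) == 1
  fit <- aov(value ~ membrane * conc, data = d)
  if (balanced) {
    sm <- summary(fit)[[1]]
    tab <- tibble::tibble(
      term = c("membrane", "conc", "membrane:conc", "Residuals"),
      df = sm[["Df"]], sumsq = sm[["Sum Sq"]], meansq = sm[["Mean Sq"]],
      statistic = sm[["F value"]], p.value = sm[["Pr(>F)"]]
    )
  } else {
    warn("Unbalanced design: using a Type-II sum-of-squares decomposition.")
    a2 <- car::Anova(fit, type = 2)
    tab <- tibble::tibble(
      term = rownames(a2), df = a2[["Df"]], sumsq = a2[["Sum Sq"]],
      meansq = a2[["Sum Sq"]] / a2[["Df"]],
      statistic = a2[["F value"]], p.value = a2[["Pr(>F)"]]
    )
  }
  structure(list(table = tab, fit = fit, balanced = balanced,
                 df_residual = df.residual(fit),
                 ms_residual = tab$meansq[tab$term == "Residuals"]),
            class = "memphys_anova")
}

#' @export
print.memphys_anova <- function(x, ...) {
  cat("<memphys_anova> two-way fixed-effects ANOVA",
      if (!x$balanced) "(Type-II, unbalanced)" else "", "\n")
  print(x$table)
  invisible(x)
}

#' @rdname two_way_anova
#' @param x A `memphys_anova` object.
#' @param ... Unused.
#' @method tidy memphys_anova
#' @export
tidy.memphys_anova <- function(x, ...) x$table

#' @rdname two_way_anova
#' @method glance memphys_anova
#' @export
glance.memphys_anova <- function(x, ...) {
  tibble::tibble(df_residual = x$df_residual, ms_residual = x$ms_residual,
                 balanced = x$balanced)
}

#' Significance stars at the study's thresholds
#'
#' Maps p values to the star convention `*` < 0.05, `**` < 0.01,
#' `***` < 0.001, `****` < 0.0001 (empty string when not significant).
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE) |>
    as.character()
}

#' Tukey HSD pairwise comparisons within a family
#'
#' Studentized-range post hoc comparisons using the residual mean square of
#' the full two-way fit. Two families mirror the study's figure captions:
#' `"conc_within_membrane"` compares concentration groups inside each
#' membrane model; `"membrane_within_conc"` compares membrane models at
#' each concentration. For each pair the studentized range statistic is
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{MS_{res}/n}} and p values come
#' from the studentized range distribution with the family's group count
#' and the residual df.
#'
#' @param tbl Tidy table as for [two_way_anova()].
#' @param within `"conc_within_membrane"` (default) or
#'   `"membrane_within_conc"`.
#' @param anova Optionally a precomputed [two_way_anova()] result for the
#'   same table.
#' @return A tibble with one row per pair: the conditioning level, `group1`,
#'   `group2`, `diff` (mean difference), `q`, `p.value` and `stars`.
#' @examples
#' tbl <- gen_study_dataset(n_replicates = 3, seed = 1) |>
#'   dplyr::filter(observable == "pf")
#' tukey_hsd(tbl)
#' @export
tukey_hsd <- function(tbl, within = c("conc_within_membrane",
                                      "membrane_within_conc"),
                      anova = NULL) {
  within <- match.arg(within)
  anova <- anova %||% two_way_anova(tbl)
  d <- data.frame(membrane = factor(tbl$membrane), conc = factor(tbl$conc),
                  value = tbl$value)
  by <- if (within == "conc_within_membrane") "membrane" else "conc"
  grp <- if (within == "conc_within_membrane") "conc" else "membrane"
  ms <- anova$ms_residual
  dfres <- anova$df_residual
  fam <- split(d, d[[by]])
  purrr::map_dfr(names(fam), function(lev) {
    dd <- fam[[lev]]
    means <- tapply(dd$value, dd[[grp]], mean)
    ns <- tapply(dd$value, dd[[grp]], length)
    k <- length(means)
    if (k < 2) abort("Fewer than 2 groups to compare.",
                     class = "memphys_bad_design")
    pairs <- utils::combn(names(means), 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      # Tukey-Kramer standard error for (possibly) unequal n
      se <- sqrt(ms / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
      diffm <- means[[g2]] - means[[g1]]
      q <- abs(diffm) / se
      pv <- 1 - ptukey(q, nmeans = k, df = dfres)
      tibble::tibble(!!by := lev, group1 = g1, group2 = g2,
                     diff = diffm, q = q, p.value = pv,
                     stars = p_stars(pv))
    })
  })
}
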