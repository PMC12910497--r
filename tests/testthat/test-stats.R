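make_table <- function(values_fun, membranes = c("A", "B", "C"),
                       concs = c(0, 1, 5, 10, 20, 40), n = 3) {
  grid <- expand.grid(membrane = membranes, conc = concs,
                      replicate = seq_len(n), stringsAsFactors = FALSE)
  grid$value <- values_fun(grid)
  grid
}

test_that("normalisation maps controls to one and scales linearly", {
  tbl <- data.frame(membrane = "DOPC", conc = c(0, 40, 40),
                    value = c(73, 83, 0))
  out <- normalize_to_control(tbl)
  expect_equal(out$rel_value, c(1, 83 / 73, 0))
  expect_equal(out$rel_value[2], 1.137, tolerance = 1e-3)
  expect_error(normalize_to_control(data.frame(membrane = "x", conc = c(0, 1),
                                               value = c(0, 5))),
               class = "memphys_missing_control")
  # the control error bar convention: relative SD of raw control replicates
  raw <- data.frame(membrane = "m", conc = rep(c(0, 10), each = 4),
                    value = c(70, 72, 74, 76, 80, 81, 82, 83))
  out2 <- normalize_to_control(raw)
  expect_equal(sd(out2$rel_value[raw$conc == 0]),
               sd(raw$value[raw$conc == 0]) / mean(raw$value[raw$conc == 0]))
})

test_that("two-way ANOVA equals brute-force sums of squares on balanced tables", {
  # tiny 2x2 hand-checkable table
  toy <- data.frame(membrane = rep(c("A", "B"), each = 4),
                    conc = rep(c(0, 1), times = 4),
                    value = c(1, 2, 2, 3, 3, 4, 5, 7))
  res <- two_way_anova(toy)
  bf <- brute_force_ss(toy$membrane, toy$conc, toy$value)
  tab <- tidy(res)
  expect_equal(tab$sumsq[tab$term == "membrane"], bf$ss_a, tolerance = 1e-12)
  expect_equal(tab$sumsq[tab$term == "conc"], bf$ss_b, tolerance = 1e-12)
  expect_equal(tab$sumsq[tab$term == "membrane:conc"], bf$ss_ab,
               tolerance = 1e-12)
  expect_equal(tab$sumsq[tab$term == "Residuals"], bf$ss_res,
               tolerance = 1e-12)
  expect_equal(sum(tab$sumsq), bf$ss_tot, tolerance = 1e-12)
  expect_equal(sum(tab$df), nrow(toy) - 1)
  # full-size randomized table
  set.seed(5)
  tbl <- make_table(function(g) rnorm(nrow(g), 10 + g$conc / 10, 1))
  res2 <- two_way_anova(tbl)
  bf2 <- brute_force_ss(tbl$membrane, tbl$conc, tbl$value)
  tab2 <- tidy(res2)
  expect_equal(tab2$sumsq,
               c(bf2$ss_a, bf2$ss_b, bf2$ss_ab, bf2$ss_res),
               tolerance = 1e-10)
})

test_that("identical values give zero effect sums of squares", {
  tbl <- make_table(function(g) rep(7, nrow(g)))
  tab <- tidy(two_way_anova(tbl))
  expect_equal(tab$sumsq, rep(0, 4), tolerance = 1e-20)
})

test_that("unbalanced designs warn and fall back to a type-II decomposition", {
  tbl <- make_table(function(g) rnorm(nrow(g)), n = 3)
  tbl <- tbl[-1, ]
  expect_warning(res <- two_way_anova(tbl), "Type-II")
  tab <- tidy(res)
  expect_true(all(tab$p.value[!is.na(tab$p.value)] >= 0 &
                    tab$p.value[!is.na(tab$p.value)] <= 1))
  expect_error(two_way_anova(tbl[tbl$replicate == 1, ]),
               class = "memphys_bad_design")
})

test_that("the concentration effect is detected with high power at d = sigma", {
  set.seed(11)
  rej <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    tbl <- make_table(function(g) {
      rank_c <- match(g$conc, c(0, 1, 5, 10, 20, 40)) - 1
      rnorm(nrow(g), mean = rank_c, sd = 1) # d/sigma = 1 per rank step
    })
    tab <- tidy(two_way_anova(tbl))
    rej <- rej + (tab$p.value[tab$term == "conc"] < 0.05)
  }
  expect_gt(rej / n_sim, 0.9)
})

test_that("Tukey limits: identical means give p near one", {
  tbl <- make_table(function(g) rep(3, nrow(g)))
  tbl$value <- tbl$value + rep(c(-0.01, 0, 0.01), length.out = nrow(tbl))
  out <- tukey_hsd(tbl)
  expect_true(all(out$p.value > 0.999))
})

test_that("with two groups Tukey reduces to the pooled two-sample t test", {
  set.seed(21)
  tbl <- make_table(function(g) rnorm(nrow(g), ifelse(g$membrane == "A", 0, 1)),
                    membranes = c("A", "B"), concs = c(0, 10), n = 5)
  an <- two_way_anova(tbl)
  out <- tukey_hsd(tbl, within = "membrane_within_conc", anova = an)
  for (j in seq_len(nrow(out))) {
    sel <- tbl$conc == out$conc[j]
    mA <- mean(tbl$value[sel & tbl$membrane == "A"])
    mB <- mean(tbl$value[sel & tbl$membrane == "B"])
    tstat <- abs(mB - mA) / sqrt(an$ms_residual * (1 / 5 + 1 / 5))
    p_t <- 2 * pt(-tstat, an$df_residual)
    expect_equal(out$q[j], tstat * sqrt(2), tolerance = 1e-12)
    expect_equal(out$p.value[j], p_t, tolerance = 1e-9)
  }
})

test_that("Tukey p values match a numerical studentized-range oracle", {
  set.seed(33)
  tbl <- make_table(function(g) rnorm(nrow(g), ifelse(g$membrane == "A", 0.8, 0)),
                    membranes = c("A", "B", "C"), concs = c(0, 10), n = 4)
  an <- two_way_anova(tbl)
  out <- tukey_hsd(tbl, within = "membrane_within_conc", anova = an)
  for (j in seq_len(nrow(out))) {
    p_or <- 1 - ptukey_oracle(out$q[j], k = 3, df = an$df_residual)
    expect_equal(out$p.value[j], p_or, tolerance = 1e-3)
  }
})

test_that("Tukey p decreases as the mean difference grows", {
  base <- make_table(function(g) rnorm(nrow(g), 0, 1),
                     membranes = "A", concs = c(0, 10), n = 6)
  an0 <- NULL
  ps <- vapply(c(0.5, 1, 2, 4), function(d) {
    tbl <- base
    tbl$value <- tbl$value + d * (tbl$conc > 0)
    # fixed noise realisation, growing separation
    suppressWarnings(out <- tukey_hsd(
      dplyr::bind_rows(tbl, dplyr::mutate(tbl, membrane = "B"))))
    min(out$p.value)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("star annotations follow the reported thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 5e-4, 5e-5)),
               c("", "*", "**", "***", "****"))
})
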