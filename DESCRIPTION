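Package: memphys
Title: Model-Membrane Biophysics: Droplet-Interface-Bilayer Permeametry,
    Tensiometry, Calorimetry and Raman Band Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tidy analysis chains for nonspecific small-molecule/membrane
    interaction studies on model lipid membranes. Implements osmotic water
    permeability estimation from droplet-interface-bilayer (DIB) shrink/swell
    traces (forward ODE model plus initial-rate and ODE-fit estimators),
    two-droplet spherical-cap contact geometry and droplet-pair image
    segmentation, bilayer tension from monolayer tension and contact angle,
    DSC thermogram reduction (baseline subtraction, main transition
    temperature, enthalpy, peak width), Raman C-H stretching band-ratio
    analysis with reference-spectrum subtraction, control normalisation, and
    the study-level two-way ANOVA with Tukey HSD post hoc comparisons.
    Seeded synthetic-data generators emulate every instrument input so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
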