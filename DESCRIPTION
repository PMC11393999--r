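Package: jc1screen
Title: Image-Based JC-1 Mitochondrial Membrane Potential Screening for
    Daphnia magna
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated high-content screening pipeline for quantifying
    mitochondrial membrane potential in Daphnia magna from multiwell-plate
    JC-1 fluorescence image stacks. Whole organisms are segmented from
    transmitted-light images, the mask is applied to the Cy3 (J-aggregate)
    and FITC (monomer) channels with pixel-level saturation exclusion, and
    per-individual red/green ratios are aggregated across z-levels under
    plate quality-control rules. Normalized ratios and immobilization counts
    are fitted with constrained two- and four-parameter log-logistic
    concentration-response models to estimate EC10 and EC50 with 95%
    confidence intervals. A synthetic plate generator with analytic ground
    truth supports end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
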