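Package: instarmix
Title: Larval Instar Determination from Head-Capsule-Width Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Determines the number of larval instars of an insect from
    per-individual head-capsule-width (HCW) measurements. Fits univariate
    Gaussian mixtures to the raw widths by maximum likelihood (EM), selects
    the number of components by BIC, places instar boundaries at the
    intersections of adjacent weighted normal curves, validates the
    partition with within-instar coefficients of variation and Brooks'/
    Crosby's growth-ratio indices, and checks Dyar's rule by log-linear
    regression of mean HCW on instar number. Includes a seedable synthetic
    HCW generator for parameter-recovery studies and tidy/ggplot2 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
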