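Package: biocogs
Title: Cost-of-Goods Modelling for Uricase Bioprocesses Under Uncertainty
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent, calibratable cost-of-goods (CoG/g) engine for
    comparing uricase manufacturing flowsheets: conventional three-column
    chromatographic purification, aqueous two-phase extraction (ATPS), and
    ATPS with PEG back-extraction recycle. Provides deterministic CoG/g with
    category breakdowns, one-at-a-time tornado sensitivity analysis over
    best/base/worst scenarios, Monte Carlo uncertainty analysis with
    triangular parameter distributions and moving-average convergence, a
    two-stage aqueous two-phase back-extraction mass balance with
    steady-state recycle credits, and linear response-surface surrogates with
    inter-process overlap analysis. All results are returned as tibbles and
    fitted surrogates support tidy() and glance().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
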