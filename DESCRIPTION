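Package: optophos
Title: Simulation and Downstream Analysis of Optogenetic Phosphoproteomic
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phosphoproteomic time courses driven by
    optogenetic kinase activation. Provides a mechanistic generator of
    synthetic light-driven Akt1 phosphoproteomes with known ground truth
    (piecewise-analytic activation kinetics, downstream substrate classes,
    log-normal measurement noise, planted sequence motifs and kinase
    annotations), a tab-separated data model for quantification, design and
    site-annotation tables, and the downstream statistics: covariate-adjusted
    trait attribution by per-site linear-model F-tests, matched paired
    t-tests across stimulation intensities with fold-change gating and
    hierarchical profile clustering, fuzzy c-means temporal clustering,
    phospho-motif and kinase-substrate Fisher enrichment, covariation-based
    substrate discovery against a reference activation site, and two-series
    polynomial time-course differential testing with profile partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
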