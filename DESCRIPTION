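Package: ciliashift
Title: Coordinated Down-Regulation Testing for Ciliary Gene Sets in
    Case-Control Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting coordinated directional
    expression shifts of predefined gene sets in small two-group
    microarray studies, modelled on bronchial-biopsy profiling of
    primary ciliary dyskinesia (PCD) patients versus controls.
    Implements intensity flooring and log2 scaling, optional quantile
    normalization, probe-to-gene aggregation, a fold-change plus t-test
    differential-expression screen, per-gene one-tailed exact
    Wilcoxon-Mann-Whitney tests combined across a gene set by the
    unweighted Z-method (Stouffer), an exact binomial set-membership
    enrichment test, leave-one-out case-sample robustness analysis, and
    a log-normal synthetic-data generator with a simulation harness for
    type-I error, power and effect-size recovery. Ships reference
    differential-expression tables for 37 axonemal genes (outer and
    inner dynein arms, radial spokes, intraflagellar transport) and 24
    PCD disease genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
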