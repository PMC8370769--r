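Package: phosflow
Title: Quantitative Phosphoproteomics Time-Course Analysis of the
    Oocyte-to-Embryo Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiplexed isobaric-label (TMT) phosphoproteomics
    time courses: peptide-to-protein rollup, internal-standard and channel
    loading normalization, unit-interval scaling, localization and
    replicate-correlation filtering, hierarchical clustering of temporal
    trajectories, phosphosite sequence-window classification (SP/TP, +2
    residue class), motif enrichment logos, Kolmogorov-Smirnov comparison of
    dephosphorylation distributions, RVxF and RxRxxS/T short-linear-motif
    scanning, treatment-response classification, and cross-dataset stage
    alignment via conserved marker phosphosites. A synthetic multiplexed
    time-course generator with planted temporal and motif structure supports
    end-to-end recovery testing without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
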