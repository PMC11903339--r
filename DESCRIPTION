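Package: morphoscreen
Title: Analysis of Optical Pooled CRISPR Screens with Morphological Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end statistical analysis of optical pooled CRISPR
    screens read out by Cell Painting-style morphological profiling.
    Provides a seeded synthetic screen generator with planted,
    compartment-structured knockout effects; sgRNA barcode library design
    and verification under in situ sequencing deconvolution and
    Levenshtein error-detection constraints; single-cell to guide- and
    gene-level profile aggregation, per-plate standardization, redundancy
    feature selection and PCA reduction; per-feature Mann-Whitney hit
    calling against nontargeting controls with empirical false discovery
    control from zero-expression null genes; mean average precision
    profile-strength scoring; protein-complex and link-score
    benchmarking; single-feature genome-wide screens with Fisher
    enrichment and granularity spectra; and Ward-ordered comparative
    correlation heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
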