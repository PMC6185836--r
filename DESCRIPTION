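Package: heterosisr
Title: Heterosis Quantification and Genetic Mapping in Common-Reference
    Hybrid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hybrid vigour (heterosis) in panels of F1 hybrids
    that share a common reference parent, and maps its genetic basis.
    Computes mid-parent and better-parent heterosis, broad-sense
    heritability and genetic coefficients of variation from replicate-level
    phenotype tables; trait-by-trait, cross-population and
    genetic-distance correlation analyses; establishment-normalised
    growth-curve heterosis for projected leaf area; and a
    kinship-corrected mixed-model association scan with dominant and
    additive SNP encodings, minor-allele-frequency filtering and
    Benjamini-Hochberg false-discovery-rate control. Includes a synthetic
    common-reference panel generator with known additive and dominance
    architecture so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
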