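Package: ishquant
Title: Quantification of HER2 Dual-Colour Bright-Field in Situ Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis toolkit for bright-field dual-colour in situ
    hybridization (ISH) of the HER2 gene in breast cancer. Segments
    hematoxylin-counterstained nuclei, separates the silver (HER2, black) and
    red (CEP17) chromogens, detects and counts discrete hybridization signals
    with doublet and cluster handling, applies the 30-150 square-micron
    nuclear size gate and the one-copy-each scoring rule, and classifies
    cases into the five ASCO/CAP breast ISH groups with 95% margins of error
    on the per-cell means. Ships a deterministic synthetic-slide generator
    with per-nucleus ground truth, validation statistics (Cohen's kappa,
    Bland-Altman limits of agreement, Bayes predictive values at a stated
    prevalence, power-model margin-of-error curves and a minimum-cell
    solver), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
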