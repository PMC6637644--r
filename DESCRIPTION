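Package: silacdiff
Title: Differential Regulation Analysis for SILAC Co-Culture Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a z-score based differential-regulation pipeline for
    multi-channel SILAC (stable isotope labeling by amino acids in cell
    culture) protein quantification tables, as used to screen proteins
    changed by hematopoietic-cell/stromal-cell co-culture. Per-replicate
    heavy-over-light (or heavy-over-medium) ratios are log2-transformed and
    standardized against the population mean and standard deviation; proteins
    are called up- or down-regulated by a dual fold-change plus z-score
    criterion with 95/99/99.9 percent confidence tiers, and final calls
    require agreement across two biological replicates. Includes gene-set
    over-representation testing (one-sided hypergeometric with
    Benjamini-Hochberg FDR control) over GMT gene-set files, a synthetic
    protein-group data generator with known ground truth for benchmarking,
    ranked reporting of top regulated proteins, and replicate scatter plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
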