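Package: panelscreen
Title: Predictive Gene Panel Screening for Two-Group Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-analysis screening of gene panels in two-group bulk and
    single-cell expression data. Genes are ranked by mutual information
    between discretized expression and a binary group label using
    Sturges-rule adaptive binning with a per-bin support guard. The
    predictive power of ranked, user-defined, random, or all-gene panels
    is estimated with Monte Carlo cross-validated multilayer-perceptron
    classification (balanced accuracy and misclassification counts), and
    gene-subset space is searched for compact high-accuracy panels by
    exhaustive enumeration, greedy forward selection, beam search, and
    swap refinement. Includes loaders for AnnData-on-HDF5 (.h5ad) and a
    labeled CSV dialect, a synthetic two-group data generator with
    planted markers and dropout, and publication-style reporting to CSV
    and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    ggplot2,
    parallel,
    readr,
    rhdf5,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
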