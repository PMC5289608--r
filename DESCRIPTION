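Package: ictair
Title: Iterative Contextual Refinement of Regulator Target Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-sample transcriptional activity of regulators
    (transcription factors and microRNAs) from their target gene lists and
    a gene expression matrix, using a Kolmogorov-Smirnov-like running-sum
    statistic over expression-sorted genes normalized against a permutation
    null (the individual Regulatory Activity Score, iRAS). Iteratively
    prunes target genes whose expression fails to rank-correlate with the
    inferred activity, yielding stable, context-refined regulons. Includes
    gene-set (GMT) and expression-matrix input/output, construction of
    directed regulator-to-regulator networks from refined target lists, a
    synthetic-data generator with planted regulons for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    igraph
Config/testthat/edition: 3
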