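Package: brmtls
Title: Immune Deconvolution and Tertiary Lymphoid Structure Analysis for
    Brain Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the tumor immune microenvironment of
    brain metastases (BrM). Provides marker-based immune cell deconvolution
    of bulk RNA-seq (MCP-counter-style population scores, immune cell
    infiltration score, immune-class clustering), construction and
    geometric-mean scoring of a tertiary lymphoid structure (TLS) gene
    signature with TLS class assignment and median high/low stratification,
    rule-based spatial TLS calling from phenotyped multiplex
    immunofluorescence cell maps (density-based aggregate detection,
    perivascular test, B-cell predominance and maturity rules), and the
    downstream association and survival statistics (Mann-Whitney U,
    Kruskal-Wallis, Benjamini-Hochberg correction, Pearson correlation,
    RNA-vs-tissue concordance, Kaplan-Meier/log-rank, Cox proportional
    hazards, logistic enrichment). A synthetic-cohort generator with known
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
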