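Package: casteToolkit
Title: Cross-Species Caste Transcriptomics: Orthogroup Harmonisation,
    Fixed-Dispersion Differential Expression and SVM Toolkit Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparative brain-transcriptome analysis of
    social-insect castes across species. Harmonises per-species gene-level
    counts onto orthogroup rows (isoform collapse, missing-species fill),
    normalises expression onto a species-free [-1, 1] scale (TPM, log,
    quantile normalisation, species-mean scaling), calls caste-biased genes
    from pooled single replicates with a fixed-dispersion negative-binomial
    conditional exact test, quantifies cross-species overlap of caste-biased
    gene sets against permutation and hypergeometric nulls, and runs
    leave-one-species-out and group-transfer support-vector-machine
    experiments with regression-based feature selection to extract a
    "genetic toolkit" for caste. Includes a synthetic multi-species
    two-caste count simulator with planted ground truth so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    e1071,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
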