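Package: clonotrace
Title: Longitudinal Tumor Subclone Detection from Expression-Inferred Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects minor therapy-resistant tumor subclones at diagnosis by
    jointly clustering paired diagnosis/relapse single cells on
    expression-inferred copy number profiles. Provides a negative-binomial
    synthetic scRNA-seq generator with planted clonal CNV architectures,
    per-cell quality control and Leiden clustering, marker-based malignant
    cell identification, reference-normalized chromosome-smoothed CNV
    inference with a six-state hidden Markov model, longitudinal subclone
    composition and resistance classification, precursor matching via shared
    non-diploid segments, bulk-segment concordance by 100 kb binning with
    Spearman correlation, and downstream statistics (Wilcoxon differential
    expression, preranked gene set enrichment, cell-cycle phase scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
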