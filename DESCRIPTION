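Package: picount
Title: Paired-Insertion Counting and Model-Based Inference for Single-Nucleus ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Uniform quantification of single-nucleus ATAC-seq fragment files
    with Paired-Insertion Counting (PIC), alongside the classical
    insertion-based and fragment-based counting strategies. Provides the
    size-filtered signed Poisson (ssPoisson) probability model for
    per-region Tn5 insertion rates, zero-adjusted estimation of per-region
    open probabilities and per-cell capture rates, moment and maximum
    likelihood insertion-rate estimators, a generalized likelihood ratio
    test for differentially accessible regions with FDR control, a
    fragment-level generative simulator of the ATAC mechanism (Bernoulli
    insertions, Tn5 primer configuration, size selection, capture
    thinning), and an evaluation harness for type I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
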