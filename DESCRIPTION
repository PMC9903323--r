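Package: lfqpipe
Title: Downstream Analysis of Label-Free Quantitative Proteomics Data
Version: 0.1.0
Authors@R:
    person("LFQ", "Pipeline Maintainers", email = "maintainers@lfqpipe.org",
           role = c("aut", "cre"))
Description: Downstream analysis of label-free quantitative proteomics:
    parsing of peptide-level reports (generic long, MaxQuant-style wide and
    DIA-NN-style long layouts), replicate-based feature selection, a family
    of mode- and variance-based within/between-group normalizations
    (including protein-level mode-between scaling applied to peptide data),
    peptide-to-protein rollup by summation, Tukey median polish or
    MaxLFQ-style pairwise-ratio reconstruction, empirical-Bayes moderated
    t-statistics with optional peptide-count-aware variance priors,
    permutation-based foldchange thresholds, spike-in benchmarking (partial
    AUC at 95 percent specificity, background foldchange centering) and a
    ground-truth spike-in simulator with power-law peptide counts and
    left-censored missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
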