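Package: molal
Title: Bayesian Active Learning for Molecular Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pool-based Bayesian active learning for binary molecular
    property prediction. Implements a Monte-Carlo-dropout Bayesian neural
    network over molecular fingerprints or precomputed embeddings, BALD and
    EPIG acquisition functions with a uniform baseline, Bemis-Murcko
    scaffold splitting, feature-space separability diagnostics, and an
    evaluation suite (average precision, expected calibration error,
    cumulative positive-acquisition curves, paired Wilcoxon comparisons and
    stable-significance analysis), together with a synthetic-data generator
    that emulates structured versus scattered representation spaces under
    class imbalance and missing multitask labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, withr, Rcpp, ChemmineR, ChemmineOB
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
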