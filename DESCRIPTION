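Package: pacemg
Title: Phase-Amplitude Coupling Features and Subject-Level Diagnostics for
    High-Density Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and diagnostic evaluation for multi-channel
    surface electromyography (HD-sEMG). Implements phase-amplitude coupling
    comodulograms from a complex Morlet transform and Welch coherence, the
    sixteen classic time- and frequency-domain EMG features, db4 wavelet
    subband features, Jeffries-Matusita class separability, a feedforward
    neural-network classifier evaluated under leave-one-subject-out
    validation with subject-level probability aggregation, and a diagnostic
    statistics stack (Wald and Bayesian intervals, diagnostic odds ratio,
    prevalence-adjusted positive predictive value, McNemar, Friedman and
    Wilcoxon tests, AUC-based sample size). A seeded synthetic HD-sEMG
    cohort generator with injectable coupling stands in for non-public
    clinical recordings and supports end-to-end pipeline runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
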