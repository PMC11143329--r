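Package: fibertune
Title: Symptom-Specific Fiber Filtering and Stimulation Tuning for Deep
    Brain Stimulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps symptom-specific white-matter circuits from deep brain
    stimulation (DBS) cohorts and tunes stimulation parameters against
    them. Streamlines of a tractography atlas are screened and rank
    correlated (mass-univariate Spearman with false-discovery-rate
    control) against per-symptom clinical improvements using the peak
    electric-field magnitude each streamline receives from every
    patient's stimulation field. The resulting symptom-network library
    supports baseline-weighted network blending to estimate motor
    improvement of unseen patients, a cross-validation and permutation
    validation battery, and a constrained derivative-free optimizer that
    suggests per-contact cathodic currents maximizing the weighted
    estimated improvement. Includes an analytic point-source electric
    field model, TRK/TCK/NIfTI input and output, and a ground-truth
    synthetic data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
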