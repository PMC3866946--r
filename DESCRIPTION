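Package: efindex
Title: Endometriosis Fertility Index, r-AFS Staging and Diagnostic
    Accuracy for IVF Outcome Prediction
Version: 0.1.0
Authors@R:
    person("efindex", "maintainers", email = "efindex@example.org",
           role = c("aut", "cre"))
Description: Computes revised American Fertility Society (r-AFS)
    endometriosis point scores and stages and the Endometriosis Fertility
    Index (EFI) from structured surgical and clinical records; compares
    prognostic indices against binary IVF outcomes with empirical ROC
    curves, Mann-Whitney AUC, Hanley-McNeil standard errors and
    Youden-optimal cut-offs; runs the two-group comparison battery
    (uncorrected Pearson chi-square, pooled t, tie-corrected Mann-Whitney)
    used in diagnostic-accuracy cohort studies; plans sample size for
    paired diagnostic designs; and generates fully synthetic patient
    cohorts so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
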