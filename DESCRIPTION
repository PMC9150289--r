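Package: concur
Title: Concurrent Copy-Number and Expression Gene Discovery with Prognostic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates marker-level copy-number log-ratio profiles with gene
    expression to identify "concurrent" genes whose DNA dosage and
    transcription change coherently. Provides circular binary segmentation
    with outlier smoothing and level merging, five-state CNV calling against
    per-array MAD thresholds, GISTIC-style recurrent-aberration scoring with
    a resampled null, per-gene Spearman concurrency tests combined across
    cohorts by Fisher's z transformation, a supervised principal-component
    survival risk model with leave-one-out cross-validated risk grouping,
    time-dependent AUC, and a panel of permutation-tested classifiers for
    dichotomous outcomes. Includes a synthetic paired-cohort generator with
    known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, survival, e1071, class
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
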