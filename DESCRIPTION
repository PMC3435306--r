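Package: maldirf
Title: MALDI-TOF Profile Spectrum Processing and Random Forest Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovery pipeline for low-molecular-weight biofluid proteome
    profiling by linear MALDI-TOF mass spectrometry. Simulates labeled
    profile-spectrum cohorts with known ground truth, preprocesses raw
    spectra (resampling, rolling-minimum baseline correction, total ion
    count normalization, quality control), detects peaks on the cohort mean
    spectrum and quantifies a samples-by-peaks feature matrix, classifies
    case versus control with a Random Forest (out-of-bag vote fractions,
    mean-decrease-in-accuracy importance), selects biomarker panels by
    median-MDA recursive feature elimination scored under repeated
    stratified 10-fold cross-validation, and screens peaks univariately by
    two-sided Wilcoxon rank-sum tests and fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
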