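Package: tfhrv
Title: Time-Frequency Heart Rate Variability Analysis of Exercise Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the autonomic response to incremental
    exercise testing from beat-to-beat heart rate data. Beat series are
    resampled and filtered, analysed with a smoothed pseudo Wigner-Ville
    distribution, and summarised as low- and high-frequency band powers,
    where the high-frequency band follows the instantaneous respiratory
    frequency tracked from R-peak amplitude modulation (ECG-derived
    respiration). Per-protocol one-minute window averages yield a feature
    matrix per cohort, which feeds a classification workflow: feature
    standardisation, adaptive synthetic oversampling of the minority
    class, two-step feature selection (bootstrap ReliefF filtering
    followed by a floating LDA wrapper with appearance-count
    thresholding), and linear discriminant classification evaluated by
    repeated stratified cross-validation and ROC analysis. A synthetic
    recording and cohort generator with known ground truth supports
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
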