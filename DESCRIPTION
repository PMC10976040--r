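Package: eegssid
Title: Seizure Detection from Scalp EEG by State-Space Model Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects epileptic seizures in multichannel scalp EEG by fitting a
    small output-only linear state-space model to every short signal epoch via
    Hankel-matrix singular value decomposition (Ho-Kalman style minimal
    realization), using the entries of the estimated state matrices as features
    for classical classifiers, and converting per-epoch predictions on
    continuous recordings into seizure events with a 30-second majority
    decision window scored as false detections per hour. Includes EDF and CSV
    annotation input/output, Butterworth band-pass and power-line notch
    preprocessing, overlapping epoching, k-fold cross-validated classifier
    evaluation, event-level reporting, and a synthetic EEG generator (colored
    background plus chirping spike-wave ictal discharges) so that the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    stats,
    utils,
    tools,
    rpart,
    randomForest,
    e1071,
    MASS,
    class,
    jsonlite,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
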