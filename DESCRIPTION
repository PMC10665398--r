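Package: stiffwave
Title: Vascular Stiffness Waveform Analysis and Evoked-Current Threshold
    Detection for Nociception Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-beat estimation of vascular stiffness (K) and viscosity (B)
    from time-aligned arterial-pressure and photoplethysmogram waveforms via a
    spring-damper mechanical impedance model; detection of the minimum evoked
    current of vascular stiffness (MEC_K) from tetanic-stimulation sessions
    using a 5 percent rise criterion with noise rejection; computation of the
    rate of change in systolic blood pressure (ROC_BP) across surgical skin
    incision; and cohort-level statistical validation (Pearson correlation,
    linear regression, iterative Smirnov-Grubbs outlier screening,
    parallel-lines ANCOVA, Bland-Altman agreement, and noncentral-F power
    analysis for sample-size planning). Includes synthetic-data generators
    with known ground truth for waveforms, stimulation sessions, and cohorts,
    so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
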