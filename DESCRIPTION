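Package: driftval
Title: Drift-Diffusion Model Simulation, Estimation and Parameter-Recovery Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating drift-diffusion (Wiener evidence-accumulation)
    model parameters through simulation and recovery. Provides the first-passage
    time machinery of the two-boundary Wiener process with trial-to-trial
    variability in drift, starting point and non-decision time; a seeded
    trial-level simulator with ready-made designs emulating three
    recognition-memory experiments (response-bias, speed-accuracy and
    encoding-strength manipulations); three parameter-estimation back-ends
    (EZ closed-form moment inversion, Kolmogorov-Smirnov distance minimization
    on signed response times, and quantile-bin chi-square minimization);
    and an end-to-end pipeline for trial trimming, signal-detection performance
    measures, participant-wise fitting with goodness-of-fit screening, group
    inference, and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
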