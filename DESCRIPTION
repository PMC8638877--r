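Package: ecitt
Title: Simulation, Scoring and Psychometrics for the Early Childhood
    Inhibitory Touchscreen Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for the Early Childhood Inhibitory
    Touchscreen Task (ECITT) and its faster-paced adult variant (ECITT-A):
    constrained pseudo-random trial-sequence generation with exact-uniform
    sampling over the valid set, generative ex-Gaussian participant models
    that produce realistic trial-level session logs, the trial-cleaning and
    inclusion pipeline with the accuracy (AccD) and reaction-time (RTD)
    inhibition difference scores, a psychometrics layer (Cronbach's alpha,
    Cohen's kappa, Welch and paired t tests with effect sizes,
    mixed/repeated-measures ANOVA with partial eta squared, bootstrap
    correlations, age-trend model comparison), and a stop-signal task engine
    with the +/-50 ms staircase and SSRT estimation under the independent
    horse-race model.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
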