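Package: facemg
Title: Simulation and Analysis of Facial EMG Empathy-for-Pain Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse facial surface electromyography
    (EMG) experiments on empathy for pain. Provides a synthetic-experiment
    generator (band-limited noise carriers with condition-dependent envelope
    modulation, mains interference and movement artifacts, pain-intensity
    ratings and trait-empathy scores with known ground truth), a Butterworth
    signal-conditioning chain (band filtering, notch comb, rectified envelope,
    event-related epoching and baseline-relative scene means), balanced
    mixed-design repeated-measures ANOVA with partial eta squared, Sidak
    corrected post hoc comparisons, paired Cohen's d, and a Benjamini-Hochberg
    screened trait-empathy correlation analysis, together with an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
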