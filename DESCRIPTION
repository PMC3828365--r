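Package: betasleep
Title: Vigilance-State-Resolved Beta-Oscillation Analysis of Rodent Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting and characterizing a pathological
    beta (15-40 Hz) oscillation in longitudinal sleep EEG/LFP recordings from
    mouse models of Huntington's disease. Provides EDF signal input/output,
    automated vigilance-state scoring from EEG, EMG and movement, Gaussian-window
    spectrograms and state-conditioned normalized power spectra, beta-peak
    detection over the fitted 1/f background, cross-channel power-power
    comodulograms, and cohort-level statistics (beta-onset ages, onset versus
    hindlimb-clasping precedence, genotype proportion chi-square, and
    genotype-by-state ANOVA). A synthetic-data generator produces sessions and
    cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
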