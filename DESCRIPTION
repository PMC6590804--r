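Package: ppspace
Title: Synthetic-EEG Pipeline for Peripersonal-Space Spectral Perturbation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for stimulus-locked EEG studies of
    peripersonal-space (PPS) perturbation. Generates synthetic multi-channel EEG
    sessions with an event-locked oscillatory ground truth (frontal theta and beta
    bursts scaling with hand-to-face proximity, a position-independent
    centroparietal alpha response, 1/f background and blink/EOG/amplitude
    artifacts), then processes them through band-pass filtering, epoching,
    threshold-based artifact rejection, Morlet wavelet event-related spectral
    perturbation (ERSP) estimation on pooled electrodes and canonical frequency
    bands, per-trial second-degree polynomial trend features, and a statistical
    layer of sign-flip permutation paired t-tests with false-discovery-rate
    correction, two-way within-subject ANOVA, and Bonferroni post-hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
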