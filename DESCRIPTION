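Package: eegret
Title: Event-Related EEG Measures and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation, preprocessing, and scoring of multi-paradigm
    event-related EEG sessions (mismatch negativity, auditory and visual
    oddball P300, 40-Hz auditory steady-state response, resting power
    spectral density), together with generalizability-theory test-retest
    reliability (variance components and G-coefficients), paired stability
    tests, and Session-by-Run repeated-measures ANOVA with
    Greenhouse-Geisser correction and polynomial trend contrasts.
    Includes a paradigm-exact synthetic-session generator with known
    ground truth for validating the full measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
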