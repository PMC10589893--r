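Package: fnirstrain
Title: In-Session fNIRS Analysis of Emotion-Regulation Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in-session functional near-infrared
    spectroscopy (fNIRS) recordings acquired during block-design
    emotion-regulation training in depression. Converts dual-wavelength
    light intensities to chromophore concentration changes via the
    modified Beer-Lambert law, cleans signals (channel interpolation,
    temporal derivative distribution repair, correlation-based signal
    improvement, band-pass filtering, spatial global-signal reduction,
    z-scoring), epochs trials into session thirds, forms training-minus-
    control contrasts per region of interest, and runs the study's
    statistical layer: repeated-measures MANOVA with polynomial contrasts
    and Huynh-Feldt correction, Benjamini-Hochberg adjustment, t-tests
    with Cohen's d, chi-squared tests of intervention frequencies, and
    lagged linear mixed models with within/between-person oxygenation
    predictors. A synthetic-cohort generator with known ground truth
    emulates the study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
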