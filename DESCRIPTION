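Package: voqual
Title: Automatic Voice-Quality Assessment from Connected Speech and
    Electroglottography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective evaluation of pathological voice quality from
    connected-speech recordings. Extracts 33 word-level and 15 global
    prosodic features (duration, energy, fundamental frequency, jitter,
    shimmer, voiced/unvoiced segmentation) from time-aligned running
    speech, computes cycle-to-cycle irregularity measures CFx and CQx
    from an electroglottographic channel, and models perceptual
    Roughness-Breathiness-Hoarseness (RBH) ratings with correlation-based
    feature selection and a sequential-minimal-optimization support-vector
    regression. Includes Krippendorff's alpha and correlation-based
    interrater-agreement statistics, seeded synthetic voice/EGG/panel
    generators for validation, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
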