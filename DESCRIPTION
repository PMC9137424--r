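Package: masksim
Title: Simulated Face-Mask Degradation of Audiovisual Speech and
    Consonant Confusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the acoustic and visual degradation of
    audiovisual speech caused by face masks, and for analyzing closed-set
    consonant identification data collected with such stimuli. Derives
    frequency-dependent mask attenuation functions from paired
    masked/unmasked recordings via Welch spectral estimation, synthesizes
    matching linear-phase FIR filters, builds calibrated speech-in-noise
    trials (speech-shaped noise, RMS equalization, SNR and nominal dB SPL
    mixing, onset/offset ramps), simulates opaque and windowed mask
    occlusion on facial-landmark video frames, and scores responses as
    confusion matrices, consonant accuracy, phonetic feature transmission
    (voicing, manner, place), and rationalized arcsine units. Includes a
    feature-channel listener simulator, cohort generators, and the
    mixed-effects inference stage (random intercept per subject,
    backward elimination of non-significant interactions, re-leveled
    post hoc contrasts, Welch's t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    lmerTest,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
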