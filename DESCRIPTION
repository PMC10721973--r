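Package: fatiguekit
Title: Multimodal Neurophysiological Assessment of Driver Mental Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying driver mental fatigue from
    multimodal physiological recordings: an EEG alpha-band Global Field Power
    drowsiness index (MDrow) built on individual alpha frequency estimation
    and three-criterion epoch screening; eyeblink rate, duration and
    amplitude from frontal-EEG-derived vertical EOG; heart rate and
    Lomb-Scargle heart-rate variability from wristband photoplethysmography;
    tonic skin conductance level from electrodermal activity; secondary-task
    reaction times and sleepiness/fatigue questionnaires. Includes a
    synthetic-session simulator that plants known fatigue dynamics with a
    full ground-truth ledger, so every analysis stage has a parameter
    recovery test, and the repeated-measures statistical procedure
    (Shapiro-Wilk gated RM-ANOVA/Friedman, Holm-corrected post-hocs,
    Segments-by-Group interaction) used to compare protocol segments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
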