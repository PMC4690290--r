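Package: bandsift
Title: Genetic-Algorithm Feature Selection for EEG Band-Power Depression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying major depressive disorder (MDD) versus
    healthy volunteers (HV) from resting-state EEG band-power features.
    Implements the full wrapper pipeline: spectral feature extraction
    (re-referencing, overlapping epochs, amplitude-based artifact
    rejection, Hann-windowed FFT band power), min-max normalization,
    genetic-algorithm feature selection with an accuracy-minus-penalty
    fitness, Fisher linear discriminant mapping to one dimension, a
    C4.5-style gain-ratio decision tree, and diagnostic-test evaluation
    (sensitivity, specificity, likelihood ratios, predictive values).
    A synthetic-data generator emulates the statistical structure of a
    53 MDD / 43 HV resting EEG study so every stage is testable without
    patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
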