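Package: logmelaci
Title: Log-Mel Acoustic Complexity Index and Diel Bird Vocalization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying diel (dawn/noon/night) differences in bird
    vocalizations from WAV recordings. Implements spectral-subtraction
    denoising, short-time energy / zero-crossing-rate endpoint detection,
    pitch-preserving time-stretch and time-shift augmentation, Log-Mel
    spectrogram and second-order MFCC feature extraction, the traditional
    Acoustic Complexity Index and its Log-Mel variant computed on a 20-band
    log-compressed Mel spectrogram, a two-layer species-then-period
    classifier with standard evaluation metrics, and seeded synthetic
    fixture generators (tones, FM chirp syllable trains, colored noise,
    labeled diel datasets) for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    nnet,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
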