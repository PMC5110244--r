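Package: epipulse
Title: Pulsatile Constriction Analysis for Epithelial Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of pulsatile basal constriction in
    epithelial sheets imaged by time-lapse microscopy. Provides watershed
    segmentation of membrane channels with overlap-based cell tracking,
    per-cell oscillation statistics (dominant frequency, peak-to-peak
    constriction-rate amplitude, net area change and ratchet
    classification), FFT cross-correlation of cortical-intensity and
    area-change rates with permutation and sinusoidal surrogate nulls,
    detection and lifetime analysis of transient cortical intensity foci
    with focus-coupled contraction tests, sparse Lucas-Kanade optical-flow
    quantification of tissue retraction after laser ablation with
    stage-angle binning, and organ-scale contour and opening-angle
    measurements. A seeded synthetic-movie generator produces
    ground-truthed polygonal cell sheets, cortical intensity channels,
    focus events and post-ablation recoil movies for validation of every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
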