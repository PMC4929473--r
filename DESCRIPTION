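Package: iqrank
Title: No-Reference Image Quality Ranking for Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sorts microscopy images within a dataset by relative quality
    without a reference image. Contrast is quantified by the Shannon entropy
    of the intensity histogram computed inside a detail mask (mean-filtered
    image thresholded at a percentile), and detail, blur and noise are
    quantified by descriptive statistics of the high-frequency tail of the
    normalized image power spectrum (fMean, fSTD, MeanBin and friends).
    Includes two classical autofocus metrics (Brenner, Spectral Moments) as
    baselines, dataset-level measure normalization and composite ranking
    with order-preserving CSV output, a synthetic-data generator producing
    Gaussian-blur focus series over filament-, bead-, ramp- and noise-like
    base images, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jpeg,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
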