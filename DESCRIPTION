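Package: wtfd
Title: Fetal Heart Sound Detection and Segmentation by Wavelet-Fractal Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and segments the first (S1) and second (S2) fetal heart
    sounds in noisy fetal phonocardiogram (fPCG) recordings. The core method is
    an iterative wavelet-fractal (WT-FD) filter: an undecimated Daubechies-4
    multiresolution decomposition, energy-based discarding and selection of
    informative detail levels, a sliding-window Katz fractal dimension trace per
    level, and an iterative peak-peeling algorithm that yields complementary
    binary masks separating transient heart sounds from stationary background
    noise. The package also ships a synthetic fPCG generator with known S1/S2
    timing (fixed or arrhythmic fetal heart rates, additive white Gaussian
    noise at configurable SNR), S1/S2 labelling from systolic/diastolic gap
    asymmetry, fetal heart rate estimation, and the detection-performance
    indices Q_P, D_R and S_F for benchmarking against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
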