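Package: cvepr
Title: Decoding Toolkit for Code-Modulated Visual Evoked Potential
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end decoding framework for code-modulated visual
    evoked potential (c-VEP) EEG experiments using maximal-length binary
    stimulation sequences. Provides m-sequence code construction and
    circular shifting, a synthetic multichannel c-VEP EEG simulator,
    detrending, zero-phase bandpass filtering and surface Laplacian
    spatial sharpening on a spherical head model, correlation and
    canonical-correlation feature extraction with Bayesian linear
    discriminant analysis, compact convolutional networks for bit-sequence
    reconstruction and direct classification, Siamese metric-learning
    decoders, distance-based code decoding (Euclidean, shrinkage
    Mahalanobis, Earth Mover's Distance and radius-constrained EMD),
    temporal-shift data augmentation, leave-one-session-out
    cross-validation and the associated non-parametric statistical
    comparison battery (Friedman, Kendall's W, pairwise Wilcoxon with
    Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
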