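Package: TexConcord
Title: Texture-Feature Concordance Across MRI Acquisition Matrix Sizes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@texconcord.org",
           role = c("aut", "cre"))
Description: Quantifies how well MRI texture features survive a change of
    acquisition matrix size under a fixed field of view. Provides a synthetic
    multi-tissue phantom with a k-space-truncation acquisition simulator,
    ROI handling with +/-3 sigma intensity normalization and gray-level
    quantization, eight classical texture-feature families (co-occurrence,
    run-length, gradient, autoregressive, Haar wavelet, histogram, Gabor,
    histogram of oriented gradients; 307 features in 2D plus a 3D subset),
    Lin's concordance correlation coefficient between matrix sizes across
    subjects, per-family transition reports, and ROI signal-to-noise and
    sharpness comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, ImageAnalysis, FeatureExtraction, QualityControl
RoxygenNote: 7.3.3
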