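Package: immunotexture
Title: Ultrasound Liver Texture Classification with an Immune-Optimized SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based classification of B-mode ultrasound liver images
    into normal, cirrhosis and cancer classes. Implements paired-ROI
    preprocessing (grayscale conversion, median despeckling, percentile
    contrast stretch, Otsu binarization), gray-level cooccurrence matrix
    statistics (entropy, angular second moment, contrast), Fourier ring
    energies, a two-level hybrid wavelet decomposition with differential
    box-counting fractal dimensions, and a clonal-selection immune
    algorithm that jointly screens the 30 texture features and tunes the
    cost and kernel-width parameters of a radial-basis-function support
    vector machine. Plain grid-searched SVM, a prototype clonal-selection
    classifier and PCA+SVM baselines are included, together with a seeded
    speckle-texture simulator so the whole pipeline can be exercised
    without clinical images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
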