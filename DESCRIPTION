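Package: hyperseed
Title: NIR Hyperspectral Discrimination of Gene-Edited Rice Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A pipeline for discriminating gene-edited (e.g. CRISPR/Cas9
    TGW6 knockout) rice seeds from their wild-type acceptor lines using
    near-infrared hyperspectral images: dark/white reflectance
    calibration and ENVI cube I/O, seed segmentation and pixel-based
    morphometry, per-seed mean spectra with Daubechies-8 wavelet
    denoising, deterministic Kennard-Stone calibration/prediction
    partitioning, exploratory principal component analysis, wavelength
    selection by the successive projections algorithm and by
    PCA-loading peaks, RBF-kernel support vector machine and extreme
    learning machine classifiers, and object-wise colour-coded
    prediction maps.  A synthetic hypercube generator reproduces the
    statistical structure of such seed images so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
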