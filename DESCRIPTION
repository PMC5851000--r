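Package: rgbvi
Title: Vegetation Index Estimation from RGB Imagery by Convolutional Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based estimation of multispectral vegetation indices (NDVI,
    GNDVI, RENDVI, SAVI, EVI) from plain RGB images of crop plots. Provides a
    synthetic multi-band field simulator with known ground truth, per-pixel
    vegetation-index maps and plot-mean targets, georeferenced plot sampling
    with radiometric calibration, a small convolutional regression network
    trained by stochastic gradient descent with an inverse-decay learning-rate
    schedule, spectral/spatial/temporal ablation baselines, and an evaluation
    harness with leave-one-bay-out cross-validation, percentage-error
    statistics and robust line fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
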