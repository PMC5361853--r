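Package: ccpipe
Title: Canopy Cover Segmentation and Quality Control for Field Phenotyping Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated image-analysis pipeline for quantifying wheat canopy
    cover from nadir field images taken under variable natural illumination.
    Converts RGB (or NIR-substituted) images to colour-space planes and
    vegetation indices (ExR, ExB, NDI2, NDI3 and the product indices NDI2*a,
    NDI3*a, NDI3*V), selects global segmentation thresholds automatically with
    a row-means (muRow) profile method or Otsu's method, classifies imaging
    illumination scenarios (high versus low light contrast) from concatenated
    channel histograms with a support vector machine, routes images to
    scenario-specific supervised pixel classifiers (decision tree or SVM) or
    an unsupervised k-means segmenter, cleans masks with a median filter and
    small-object removal, and screens the resulting canopy-cover time series
    with a between-date correlation analysis. A synthetic row-crop image
    generator with ground-truth masks makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    igraph,
    jpeg,
    jsonlite,
    png,
    rpart,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
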