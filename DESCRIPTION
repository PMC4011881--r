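Package: ihcscore
Title: Automated Four-Tier Scoring of DAB-Stained Immunohistochemistry Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative evaluation of brightfield immunohistochemistry
    photomicrographs stained with 3,3'-diaminobenzidine (DAB) and a
    hematoxylin counterstain. Images are unmixed into pure-stain density
    channels by Beer-Lambert optical-density color deconvolution, the
    reconstructed DAB channel is profiled pixel-by-pixel into four
    intensity zones, and an automated four-tier pathology score (high
    positive, positive, low positive, negative) is assigned for
    cytoplasmic markers or, through a threshold-derived nuclear mask, for
    nuclear markers. Includes the inter-rater agreement statistics
    (percent agreement, Cohen's kappa with large-sample confidence
    interval, chi-square) used to validate automated scores against
    pathologist scores, and a synthetic-image generator that forward
    composes ground-truth stain-density fields for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
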