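Package: calospec
Title: Multispectral Food Classification and Caloric Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing multispectral food images captured under
    narrow-band LED illumination (ultraviolet, visible and near-infrared
    center wavelengths plus a white/RGB shot). Implements masked brightness
    histograms and Bhattacharyya-distance feasibility statistics, shot
    intensity normalization, a compact convolutional neural network for
    food-type classification (cross-entropy) and caloric regression (MAPE
    loss), and a piecewise forward-backward wavelength-subset selection
    driven by the network's validation loss. A synthetic multispectral
    image generator with planted near-infrared contrast between visually
    confusable food classes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
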