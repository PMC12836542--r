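Package: tumouroidr
Title: Image-Based Quantification of Tumouroid Growth and Drug Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive, continuous quantification of patient-derived
    tumouroid growth and chemotherapeutic response from time-lapse well-plate
    imaging. Collapses Z-stacks to best-focus projections, segments tumouroids
    with an image-specific global threshold, derives seven morphometric well
    readouts over time with intra-well day-1 normalization, and fits
    vehicle-normalized five-parameter log-logistic dose-response models with
    ED50/GI50 estimation. Includes a synthetic plate simulator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
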