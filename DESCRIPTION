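Package: tkvtools
Title: Semi-Automated Total Kidney Volume Measurement from T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures total kidney volume (TKV) in autosomal dominant
    polycystic kidney disease (ADPKD) from coronal T2-weighted abdominal MRI.
    A user-seeded hybrid level-set active contour (region force plus
    edge-weighted geodesic regularisation) segments each kidney after
    slice selection, rigid inter-slice motion correction, entropy-minimising
    bias-field correction and inter-slice gain normalisation. Also provides
    the ellipsoid and mid-slice estimating equations, Mayo imaging
    classification (1A-1E) from height-adjusted TKV and age, an agreement
    statistics suite (Bland-Altman, Dice, coefficient of variation,
    limits-of-agreement sample-size planning), and a synthetic phantom
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
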