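Package: voiquant
Title: Small-Source Activity Quantification and Lesion Dosimetry for
    Emission Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies radioactivity in small sources on reconstructed
    3D emission-tomography images (SPECT) using concentric oversized
    volumes of interest: the y-intercept of a linear fit of VOI count
    rate against VOI volume isolates counts originating from the source,
    with a closed-form standard uncertainty on the intercept.  Includes
    the two standard comparator methods (local-background VOI and
    recovery-coefficient correction with a two-parameter logistic
    recovery curve), system sensitivity calibration with decay
    correction, a seeded digital-phantom simulator (Gaussian
    point-spread blurring, Poisson counting statistics, binomial
    thinning for non-uniform backgrounds), and the downstream lesion
    dosimetry chain: mono-exponential time-activity fitting,
    time-integrated activity, and absorbed dose with first-order
    uncertainty propagation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
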