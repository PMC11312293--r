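Package: msiband
Title: Mutual-Information Band Selection and Texture Classification for
    Multispectral Image Cubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing the spectral dimensionality of multispectral
    image cubes (e.g. histopathology acquisitions spanning visible and
    near-infrared wavelengths) before texture-based tissue classification.
    Redundant bands are identified offline from the mutual information
    between adjacent bands of a sample of images: runs of high-MI bands are
    collapsed to their maximum-entropy representative and a majority vote
    across sample images fixes the retained band set.  The package also
    provides the texture descriptors the selection serves (local binary
    patterns, uniform rotation-invariant LBP, local phase quantization and
    its rotation-invariant extension), an RBF-SVM evaluation harness with
    repeated stratified 70/30 holdout, a synthetic cube generator with known
    band redundancy for validation, and readers/writers for multi-page TIFF
    and ENVI cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    kernlab,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
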