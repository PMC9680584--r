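Package: epidcal
Title: Non-Iterative Dose Calibration for Electronic Portal Imaging Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts portal images from an electronic portal imaging device
    (EPID) into absolute dose-to-water maps at the detector plane using a
    non-iterative, measurement-based calibration: a cross-calibration factor
    against an ionization chamber plus three multiplicative correction factors
    for field-size response, phantom-thickness response, and the lateral
    profile flattening applied by the vendor acquisition software. Includes
    Otsu-based field-size estimation, water-equivalent thickness handling for
    slab and two-dimensional phantoms, a 2D gamma-index validation module, a
    seeded synthetic linac-plus-EPID forward model that generates the complete
    calibration fixture set, and file formats plus a command-line interface
    for the calibrate/convert/gamma/simulate workflow.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
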