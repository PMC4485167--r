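Package: barscan
Title: Barcode-Formatted Immunoassay Readout and ODR Scanometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encode assay results as Code 39 linear barcodes, render
    synthetic barcode-formatted test-strip images with controlled optical
    density ratio (ODR), decode barcodes from raster images by scanline
    analysis for the qualitative call, and quantify analyte concentration
    scanometrically from strip darkness via the ODR statistic and a
    four-parameter logistic calibration curve. Includes a synthetic imaging
    module emulating the physical strip geometry (3 mm test line, 2 mm
    control line, 0.5 mm barrier) with optional blur, lighting gradient and
    pixel noise, plus a small command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
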