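Package: teatherm
Title: Delta Thermal Radiomics for Infrared Thermograms of Dairy Cow Teats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative analysis of colorized infrared
    thermograms of dairy cow teats. Converts 3-channel colorized thermal
    images to calibrated single-channel temperature maps (0.1 degree C
    precision, stored as unsigned integers at 10 units per degree) and
    reads/writes them as single-frame DICOM; represents, rasterizes and
    compares teat segmentations (Dice agreement with bootstrap confidence
    intervals); extracts a fully specified 851-biomarker radiomic feature
    set (shape, first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM, plus all
    eight undecimated-wavelet sub-bands) from a segmented region; screens
    pre- versus post-milking feature changes for expression (paired t-test
    plus Cohen's d); renders local sliding-window feature maps; and
    generates synthetic teat phantoms with known ground truth so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    jpeg,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
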