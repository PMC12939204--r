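Package: ribgrade
Title: Rib-Eye Grading from Calibrated Smartphone Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Non-interactive pipeline for grading beef rib-eye (longissimus
    dorsi) cross-sections from calibrated colour photographs. From an image
    with a known in-frame scale reference it extracts length, width and area
    of the muscle, the marbling (intramuscular fat) percentage via automatic
    isodata thresholding and particle analysis, and the R/(R+G+B) colour
    ratio, then assigns one of five grades (A1-A5) from interval thresholds
    on the three parameters. Includes the manual grid-paper area oracle,
    Gaussian-fit outlier elimination, Pearson agreement statistics, and a
    synthetic rib-eye image generator with exact ground truth so the whole
    method is testable without real beef images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jpeg,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
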