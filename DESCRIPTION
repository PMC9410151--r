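Package: cdmamqc
Title: Automated Contrast-Detail Phantom Scoring for Mammography and
    Breast Tomosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for image-quality evaluation of digital mammography and
    digital breast tomosynthesis (DBT) systems with a contrast-detail
    phantom of the CDMAM type. Models the phantom geometry (gold-disk
    diameter and thickness series on a -45 degree rotated grid with
    randomized peripheral disks), renders synthetic noisy exposures for 2D,
    tomographic-layer and synthesized-2D acquisition modes, scores images
    with an automated four-alternative forced-choice matched-filter
    observer, fits psychometric detection curves to obtain threshold gold
    thicknesses per disk diameter, and summarises image quality as inverse
    image-quality figures (IQF_inv), total-detected percentages and EUREF
    limit classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    EBImage,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
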