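Package: innervaquant
Title: Automated Quantification of Skin Innervation in Fluorescence Wound Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of cutaneous innervation from
    immunofluorescence images of healing skin wounds. Implements a residual
    convolutional denoiser (DnCNN) with desk-scale training, a conventional
    threshold-denoiser baseline, statistically derived positive-pixel
    classification of the PGP9.5 (pan-neuronal marker) channel via background
    estimation, median-distance outlier exclusion and a Q3-to-maximum midpoint
    threshold, region-wise nerve fiber density (positive pixels per square
    millimetre), group summaries with Welch and pooled t-tests, the
    re-epithelialization percentage, the density-versus-re-epithelialization
    correlation across a wound-healing time course, and a fully seeded
    synthetic-section generator with ground-truth fiber masks for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    png,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
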