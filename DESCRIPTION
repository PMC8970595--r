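Package: omapr
Title: Low-Cost Cardiac Optical Mapping Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for processing high-speed voltage-sensitive-dye
    fluorescence recordings of paced rodent hearts. Reads and writes a
    self-describing binary movie format (OMR1), conditions noisy inverted-
    polarity dye signals (spatial gaussian binning, beat segmentation,
    ensemble averaging, normalization, SNR mapping and pixel masking), and
    derives activation maps, APD80 maps, conduction-velocity vector fields
    by local polynomial surface fitting, and APD/CV restitution curves. A
    built-in anisotropic wave simulator generates movies with known ground
    truth (activation field, APD field, axis conduction velocities) so the
    whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
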