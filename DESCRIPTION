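Package: specdemux
Title: Numerical Demultiplexing of Color Image Sensor Measurements into
    Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous multispectral imaging with an ordinary Bayer-filter
    color sensor: characterize the sensor's per-channel spectral sensitivity,
    build the linear forward model mapping high-resolution reflectance spectra
    to RGB measurements, and learn numerical demultiplexers - Wiener estimators
    and a multi-output random forest - that invert a 3-channel measurement into
    a 61-point reflectance spectrum per pixel. Includes synthetic generators for
    sensitivity curves, reflectance spectra populations and test icons, PSNR
    evaluation harnesses for simulation and icon experiments, spectral-cube and
    band-image I/O, and a command-line interface.
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
    png,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
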