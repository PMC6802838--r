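Package: sptread
Title: Automated Reading of the Skin Prick Test from 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of skin-prick-test (SPT) wheals from
    regular-grid height maps of the forearm. Isolates wheals from the global
    arm curvature and fine skin texture by band-selective collapse of a
    Gaussian-Laplacian pyramid, detects them as scale-normalized
    Laplacian-of-Gaussian scale-space maxima, and estimates each wheal's
    longest diameter by bounded nonlinear least-squares fitting of two
    parametric surface models (an inverted elliptical paraboloid and a 2D
    super-Gaussian). Includes readers and writers for height-map grids
    (32-bit float TIFF, CSV, ASCII PLY), a synthetic phantom generator with
    known ground truth (curved forearm with super-Gaussian wheals, spherical
    caps, height staircases), and reproducibility and agreement statistics
    (coefficient of variation, Bland-Altman limits of agreement).
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
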