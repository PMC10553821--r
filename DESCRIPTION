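Package: dermadisp
Title: Mitotic Dispersal and Condensate Recruitment Analytics for Embryonic Skin Mesenchyme
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of mesenchymal cell dispersal in embryonic skin from
    time-lapse tracking tables: per-track motility statistics (speed,
    Euclidean and accumulated distance, persistence, time-ensemble mean
    squared displacement and its slope), dermal-condensate entry detection
    with windowed Fisher exact comparisons, condensate-referenced angular
    variography with exponential model fits, permutation Monte Carlo range
    tests, ordinary kriging of axial mitosis angles and local randomness
    maps, pairwise alignment coefficients for vector and axial data
    including a 2D-Fourier collagen-fibre pipeline, and an agent-based
    simulator of mitotic dispersal on a periodic domain with absorbing
    condensates. Ships seeded synthetic-data generators so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    grDevices,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    readxl,
    yaml,
    png,
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
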