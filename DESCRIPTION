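Package: planecut
Title: Cutting-Plane and Cutting-Forward-Distance Planning for Target-Hit
    Histological Sectioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans cryostat sectioning of embedded tissue blocks so that a
    single section hits the centers of several targets at once. Localizes
    target centers in a fiducial-referenced block coordinate system from
    per-section observations, constructs the expected and virtual (mirrored)
    sectioning planes and the needle-guide model that realizes the virtual
    plane, checks the plan against the cryostat's cutting-angle capacity,
    computes cutting-forward distances and trim/collect schedules, simulates
    serial sectioning of synthetic blocks, and reproduces repeatability
    statistics (coefficients of variation, correlation, paired comparison)
    for validation studies.
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
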