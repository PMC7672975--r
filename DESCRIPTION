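Package: capsim
Title: Antibody Transport Simulation in Encapsulated Tumor Microenvironment Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates antibody penetration into three-dimensional in vitro
    tumor-microenvironment capsules using a two-dimensional finite-difference
    solver for Fickian diffusion with heterogeneous diffusivity and a
    binding-site saturation law that progressively shuts down transport into
    cells. Provides a tunable stochastic generator of capsule geometries
    (cancer spheroids, fibroblasts, collagen fibers), digitization of labeled
    capsule cross-section masks, extraction of mean-concentration time
    profiles for circular regions of interest, Richards-family sigmoid
    fitting with delay-time and log-phase-slope metrics, and quasi-Newton
    calibration of the saturation parameters against observed profiles by
    normalized-profile RMSE.
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
    minpack.lm,
    optparse,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
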