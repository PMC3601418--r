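Package: climfate
Title: Multimedia Chemical Fate and Fish Bioaccumulation Under Climate-Change Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening how climate-change forcing (temperature and
    precipitation shifts) alters the environmental fate and bioaccumulation of
    neutral organic chemicals. Provides a multi-region steady-state fugacity
    mass-balance model with van't Hoff temperature corrections of partition
    coefficients and Arrhenius corrections of degradation half-lives, scanned
    over a hypothetical-chemical partitioning-space grid to produce
    perturbed-to-baseline concentration-ratio maps; and a coupled thermal
    bioenergetics and kinetic bioaccumulation model for an ectotherm fish,
    scanned over hydrophobicity and biotransformation half-life under warming
    offsets of a seasonal temperature cycle. All results are returned as tidy
    tibbles with ggplot2 autoplot methods.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
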