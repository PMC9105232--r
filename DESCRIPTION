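Package: stembark
Title: Bark Thickness, Surface and Biomass Along Stems of Young Broadleaved Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-specific allometric models for bark properties on stems of
    young broadleaved trees (common aspen, goat willow, rowan, sycamore):
    tree height, diameter at breast height, bark thickness and stem radius as
    functions of stem-base diameter and height above ground. Fitted models are
    composed with truncated-cone geometry to derive per-section bark surface
    area, bark volume, bark mass and specific surface mass along the lower
    stem profile (0-250 cm), quantities relevant to biomass accounting and to
    estimating the bark forage available to large wild herbivores. Includes
    packaged regression coefficients, nonlinear least-squares refitting of all
    model forms from per-tree and per-section data, and a seeded synthetic
    stem-population generator emulating a destructive-sampling protocol so
    that every stage is testable without field data.
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
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
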