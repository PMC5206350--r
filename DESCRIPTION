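Package: phytodev
Title: Phytomer Growth and Development Analysis for Grass Tillers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coordinated elongation of grass phytomers
    (leaf blade, sheath and internode) along a tiller. Provides a seeded
    forward simulator of tiller growth that emulates daily ruler observations
    (tip-to-ligule distances, censored inside the enclosing sheath whorl) and
    end-of-experiment dissection tables; a reconstruction pipeline that
    estimates tip-emergence times, the phyllochron, predicted final lengths
    and the normalized (fraction-of-final-length) time course of phytomer
    development; logistic growth-curve fitting with goodness-of-fit
    statistics; and per-treatment summary tables with percent treatment
    effects. All user-facing functions take and return data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
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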