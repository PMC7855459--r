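Package: batchphys
Title: Quantitative Physiology of Batch Bioreactor Cultivations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based estimation of specific growth and substrate-uptake
    rates from batch bioreactor time courses, off-gas CO2 balancing,
    instantaneous carbon balancing with Gaussian error propagation, and
    parametric Monte-Carlo bootstrap uncertainty quantification with
    Latin-hypercube measurement perturbation. Includes biovolume/cell-dry-weight
    calibration utilities and a synthetic batch-culture data generator so the
    whole pipeline can be exercised and tested without plant data.
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
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
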