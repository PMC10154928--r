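Package: flightpower
Title: Flight Power Curves and Muscle Conversion Efficiency in Bats and Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the efficiency with which flying animals convert
    metabolic power into aerodynamic work. Implements Pennycuick-style and
    flapping-flight mechanical power models with characteristic-speed solvers,
    wake-integral mechanical power from gridded particle image velocimetry
    velocity planes (vorticity masking, streamfunction flow reconstruction,
    net-drag correction, vertical-force quality control), metabolic power from
    13C-labelled sodium bicarbonate washout traces, constrained U-shaped
    power-curve mixed-model fits, four whole-animal and muscle conversion
    efficiency estimators, and a cross-species efficiency-body-mass scaling
    meta-analysis. A synthetic-data module generates every input with known
    ground truth so the full pipeline is testable without wind-tunnel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    Matrix,
    minpack.lm,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    lme4,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
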