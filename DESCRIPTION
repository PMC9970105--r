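Package: firewindow
Title: Restorative Fire-Severity Windows from Probabilistic Tree Mortality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale assessment of the capacity of wildfire to restore
    historical dry-forest structure. Fits species-level binomial mixed models
    of fire-induced tree mortality driven by remotely sensed burn severity
    (RdNBR), propagates coefficient uncertainty by Monte Carlo sampling,
    simulates post-fire stand basal area, density, and composition across the
    severity gradient, identifies restorative severity windows against
    historical reference conditions, validates predictions against independent
    plots, and reclassifies severity rasters into restoration-probability
    classes. Ships a synthetic-data generator with known ground truth so the
    whole pipeline is testable without proprietary inventory data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
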