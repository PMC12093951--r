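Package: phycocarb
Title: Carbon-Capture Accounting for Algal Carbonate-Precipitating Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carbon-capture accounting in microalgal cultures that
    precipitate calcium carbonate. Computes the Langelier Saturation Index
    (LSI) and its terms from water-chemistry panels, converts biomass and
    CaCO3 precipitate masses to equivalent CO2 via fixed stoichiometric
    factors, derives extra-CO2 percentages, precipitate yields, ash content,
    fold changes and areal productivity/capture rates from batch-culture time
    series, and ships a seeded batch-culture simulator (logistic growth with a
    bicarbonate dose response, sparging pH dynamics, and LSI-gated CaCO3
    precipitation with calcium/alkalinity mass balance) so the whole pipeline
    is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
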