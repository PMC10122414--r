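Package: erwcycle
Title: Reduced-Complexity Carbon-Cycle Modelling of Enhanced Rock Weathering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An emissions-driven coupled atmosphere-ocean-terrestrial carbon
    cycle box model for quantifying the long-term storage permanence and ocean
    co-benefits of carbon dioxide removal (CDR) through enhanced rock
    weathering (ERW). Includes a seawater carbonate-system solver (DIC and
    total alkalinity to pCO2, pH, and carbonate mineral saturation states), a
    four-box ocean with air-sea gas exchange, overturning transport, a
    biological pump and CaCO3 burial, a two-layer energy-balance climate
    response, a stochastic two-pool slab terrestrial biosphere with
    observational filtering, idealized concentration-pathway synthesis with
    emission inversion, intervention scenarios (modulated emissions versus ERW
    with silicate or carbonate feedstock), and backflux/leakage diagnostics
    together with aragonite saturation co-benefit metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
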