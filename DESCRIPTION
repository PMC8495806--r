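Package: trophicflux
Title: Energy Flux Through Trophic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes steady-state energy fluxes along the feeding links of a
    trophic network from node biomasses, body masses, metabolic demand,
    feeding preferences, and assimilation efficiencies, following the
    metabolism-centred food-web energetics approach. Provides allometric and
    temperature scaling of metabolic rates, length-mass conversion,
    biomass-weighted feeding preferences, resource-type assimilation
    efficiencies, topological aggregation of compartments, ecosystem-process
    proxies (herbivory, detritivory, predation) and trophic
    multifunctionality, Monte-Carlo sensitivity of fluxes to parameter
    uncertainty, a guild-structured synthetic community generator, and a
    command-line interface over delimited-text inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
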