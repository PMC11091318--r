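Package: bsflux
Title: Bioenergetics and Feed-Efficiency Analysis for Black Soldier Fly Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Growth and metabolic-performance models for black soldier fly
    (Hermetia illucens) larvae reared on organic residues. Implements a kinetic
    Verhulst logistic growth model with a growth/maintenance respiration split,
    a dynamic two-compartment (structural biomass and storage lipid) energy-budget
    simulator covering the feeding phase and post-prepupation lipid catabolism,
    net growth efficiency (instantaneous and lifetime-average, in carbon
    equivalents), the four mass-balance performance indicators used in
    entomoremediation studies (bioconversion rate, substrate conversion
    efficiency and ratio, substrate reduction rate), nonlinear least-squares
    parameter estimation from dry-weight, CO2-rate and lipid time series with
    multistart identifiability diagnostics, and seeded synthetic-data generators
    for larval observation series and whole rearing-experiment mass balances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
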