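Package: ranchena
Title: Mass-Balance Food-Web Modelling and Ecological Network Analysis for
    Marine Ranching Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to define, validate and solve static mass-balance
    (Ecopath-style) food-web models, compute ecological network analysis
    indices (Lindeman spine, transfer efficiency, Finn's cycling index and
    mean path length, ascendancy, connectance, system omnivory), grade
    ecosystem status by quintile-based fuzzy comprehensive evaluation,
    search ecological carrying capacity and stock-enhancement potential by
    trophic-level bins, and simulate stock-enhancement scenarios with a
    foraging-arena dynamic model. Includes a generator of balanced synthetic
    food webs for testing and transcriptions of published marine-ranching
    reference tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
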