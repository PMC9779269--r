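Package: lucsim
Title: Cellular-Automata Land Use Change Simulation and Ecosystem Service Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating land use and land cover (LULC) change with
    three cellular-automata engines (Markov-chain CA, an ANN-driven
    FLUS-style engine with adaptive inertia and roulette competition, and a
    PLUS-style engine with random-forest land expansion analysis and
    multi-type random patch seeding), for validating simulated maps against
    observations (confusion matrix, Cohen's kappa), for building
    policy-restriction scenarios, and for valuing the resulting landscapes by
    benefit transfer with per-hectare ecosystem service coefficients.
    Includes a synthetic landscape generator with known transition dynamics
    for end-to-end testing, landscape pattern metrics (Shannon diversity and
    evenness, contagion), and ordinary kriging of point observations to
    driver surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
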