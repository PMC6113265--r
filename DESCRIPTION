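Package: modses
Title: Scenario Analysis of Land-Use Change and Ecosystem-Service
    Interactions in Mountain-Oasis-Desert Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates future land-use change in arid mountain-oasis-desert
    landscapes with a Markov-chain demand model under policy scenarios
    (business-as-usual, economic development, ecological conservation) and a
    FLUS-style cellular automaton whose per-class suitability surfaces come
    from a single-hidden-layer neural network.  Quantifies six ecosystem
    services per pixel (Budyko-type water yield, Miami-type crop production,
    USLE soil conservation, RWEQ sand fixation, carbon-pool sequestration,
    survey-based aesthetic value) and identifies multi-service trade-offs and
    synergies through min-max-normalized regional trend series and a
    six-digit per-pixel overlay code with area filtering and land-use cause
    attribution.  Ships a seed-reproducible synthetic-landscape generator so
    the full pipeline is testable without geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    nnet,
    stats,
    tools,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
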