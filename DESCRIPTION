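Package: sedimeth
Title: Litter Phenols and Methane Production in Lake Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline linking plant-litter phenols to suppressed
    methanogenesis in lake sediments. Converts periodic headspace gas
    measurements from anaerobic jar incubations into cumulative CH4 and CO2
    production with dilution bookkeeping; corrects fluorescence
    excitation-emission matrices (EEMs) for inner-filter effects and fits
    nonnegative PARAFAC models with split-half validation to derive a
    relative phenol index; quantifies mcrA gene copies from qPCR standard
    curves; provides the amendment-by-spike ANOVA and log-log phenol-CH4
    regression layer; and projects ecosystem-scale CH4 production across
    Boreal Shield lakes from species-distribution-model occurrence
    probabilities with Monte Carlo uncertainty propagation. A seeded
    synthetic-data generator emulates every input so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
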