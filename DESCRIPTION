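Package: rafpa
Title: Equilibrium Models of RAF Inhibitor Paradoxical Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form equilibrium models of paradoxical activation (PA) of
    RAF kinase by ATP-competitive RAF inhibitors. Implements four nested
    thermodynamic models of RAF monomer autoinhibition, dimerization and drug
    binding (conformational autoinhibition, dimer potentiation, negative
    cooperativity, and their union), an independent detailed-balance
    equilibrium solver used to validate every closed form, dose-response
    simulation with PA fold-change/range metrics and phase maps, multi-start
    bounded fitting of the unified model to normalized dose-response panels
    with sub-model comparison and identifiability diagnostics, and a
    synthetic-panel generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
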