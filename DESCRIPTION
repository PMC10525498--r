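Package: prxcycle
Title: Kinetic Modelling of the Peroxiredoxin Dimer-Decamer Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the reversible association of peroxiredoxin
    (Prx) dimers into decamers and its consequences for peroxidase activity.
    The package enumerates the symmetry-reduced oxidation and dissociation
    network of the Prx decamer with degeneracy-scaled rate constants, builds
    mass-action ordinary differential equation models from reaction networks,
    simulates multi-injection isothermal titration calorimetry (ITC) dilution
    experiments and estimates association/dissociation rate constants from
    power traces, and simulates horseradish-peroxidase competition and
    NADPH-linked peroxidase assays for dimer-only and mixed dimer-decamer
    model variants. Reaction networks can be exported as SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
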