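Package: pocketflow
Title: Pocket-Conditioned Equivariant Flow Matching for 3D Ligand Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale SE(3)-equivariant joint continuous/discrete flow
    matching for pocket-conditioned generation of 3D small-molecule ligands.
    Ligand coordinates follow a continuous flow while atom types, formal
    charges, hybridizations and bond orders follow a discrete jump process,
    decoded by an equivariant attention backbone conditioned on a protein
    pocket. The backbone carries three output heads: structure recovery,
    four-endpoint binding-affinity regression (pIC50, pKi, pKd, pEC50) and a
    binned-lDDT confidence estimate. Generation can be steered at inference
    time by sequential Monte Carlo importance resampling toward reward-defined
    objectives, including dual-objective on-/off-target selectivity. Includes
    SDF/PDB input and output, binding-site extraction, a procedural generator
    of toy ligand-pocket complexes with an analytically known affinity ground
    truth, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
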