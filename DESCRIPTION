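Package: dimerlens
Title: NMR and Structure-Based Analysis of Protein Dimer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quaternary-state analysis of small proteins from solution NMR
    and crystallographic coordinates, developed around the CC-type chemokine
    CCL5 and its oligomerization-deficient variants. Implements secondary
    chemical-shift secondary-structure prediction (the CA-CB index with
    three-residue smoothing), amide chemical-shift-perturbation mapping with
    configurable significance tiers, 15N relaxation analysis (exponential
    R1/R2 fitting, heteronuclear NOE, rotational correlation time from the
    R2/R1 ratio, monomer/dimer classification), and coordinate-based dimer
    interface analysis: crystallographic symmetry expansion, backbone
    hydrogen-bond detection, Shrake-Rupley buried-surface area, Kabsch
    superposition, beta-sheet pairing-register comparison, and Matthews
    coefficient/solvent-content arithmetic. Includes synthetic-data
    generators that provide ground-truth fixtures for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
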