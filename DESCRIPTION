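Package: bindmap
Title: Mapping Peptide-Receptor Binding Interfaces from NMR Titrations,
    Calorimetry and Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of how a disulfide-rich peptide engages a
    receptor domain, built around the chlorotoxin (ClTx) interaction with the
    b1 domain of neuropilin-1 (NRP1-b1). Implements amide chemical-shift
    perturbation (CSP) mapping of 1H-15N HSQC titrations with mu/sigma
    significance thresholds, intensity-attenuation analysis and competitor
    displacement; exact single-site 1:1 and two-ligand competitive binding
    equilibria with thermodynamic decomposition (Kd, dH, dG, -TdS);
    simulation and fitting of isothermal titration calorimetry (ITC)
    thermograms under a discrete injection schedule; multi-model structure
    ensemble statistics (iterative superposition, RMSD to the mean
    coordinates, disulfide-framework detection, surface-patch clustering,
    restraint bookkeeping); derivation and CNS/HADDOCK-style export of
    docking restraints from CSP interface maps; and seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
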