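Package: helicard
Title: Helical CARD Filament Geometry, Interfaces, Perturbation Mapping, and
    Polymerization Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing death-domain (CARD) helical assemblies and
    their autoinhibited precursors. Reads and writes multi-model PDB
    coordinate ensembles; performs rigid-body superposition, ensemble RMSD
    statistics, screw-axis (rise/twist) decomposition and backbone dihedral
    analysis; builds and fits helical filament lattices and types
    inter-subunit interfaces by start number (Type I/II/III = 3-/4-/1-start);
    computes residue contacts, Shrake-Rupley solvent-accessible surface area
    and buried interface area; classifies NMR line broadening and chemical
    shift perturbations and estimates hydrogen-deuterium-exchange protection
    factors with residue-level consensus; and simulates
    nucleation-elongation-capping polymerization kinetics with unidirectional
    growth, interface-dead capping mutants and seeded nucleation. A synthetic
    data module generates toy protomers, noisy ensembles, peak tables and
    uptake curves so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
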