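Package: nucleakit
Title: Classical Nucleation Theory Analysis of Induction-Time Kinetics and
    Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the crystallizability of polymorphic
    organic compounds from isothermal induction-time experiments and
    molecular-dynamics conformational ensembles. Converts solubility and
    concentration data into supersaturation ratios and nucleation driving
    forces; estimates nucleation rates from replicate, right-censored
    induction times; fits the classical nucleation theory rate law to
    extract the pre-exponential kinetic factor, the thermodynamic parameter,
    the effective solid-liquid interfacial energy, the critical nucleus
    radius and size, the Zeldovich factor and the attachment frequency;
    classifies phenyl dihedral conformers, detects intramolecular hydrogen
    bonds, and computes radii of gyration and superposed RMSDs from
    multi-frame trajectories. Includes seeded synthetic-data generators so
    every stage of the pipeline is testable without external measurements,
    and ships published ritonavir form I nucleation tables as worked
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
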