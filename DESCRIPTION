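Package: bdascan
Title: Boron Delivery Antibody Site Scanning and Boronated Residue Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies antibody residues (Phe, Tyr, Trp, His) that can be
    replaced by a boronated analogue for boron neutron capture therapy carrier
    design. Implements glycine/alanine cavity scanning outside a protected
    binding interface, construction of boronic-acid fragment probes with
    literature boron geometry (boron typed as carbon for docking), a docking
    engine contract (external AutoDock-Vina-compatible adapter, deterministic
    built-in grid scan, and pose replay) with PDBQT parsing, geometric pose
    filtering by cavity assignment, reference-carbon distance, directionality
    angle and steric clash, boronated-residue (BPA) construction with
    exportable residue templates, and wild-type versus mutant trajectory
    analytics: Kabsch superposition RMSD, RMSF, geometric hydrogen-bond
    detection and conservation, and leader clustering with population
    reporting. Includes deterministic synthetic structure, pose and trajectory
    generators so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
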