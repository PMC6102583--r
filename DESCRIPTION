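Package: phorescreen
Title: Pharmacophore-Based Virtual Screening with Enrichment Statistics,
    Docking Consensus Filtering and MM-PBSA Bookkeeping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-stage ligand-based virtual screening against a
    pharmacophore hypothesis. Parses small-molecule libraries (SMILES, SDF),
    applies Lipinski drug-likeness filtering, perceives pharmacophoric feature
    points (hydrogen-bond acceptors and donors, hydrophobes, aromatic rings),
    generates conformer ensembles, maps ligands onto feature-sphere hypotheses
    with excluded volumes, and scores the overlay with a fitvalue. Screening
    hypotheses are validated with the hit rate of actives (HRA), the identify
    effective index (IEI) and the comprehensive appraisal index (CAI), and
    compared by Tanimoto fingerprint similarity. A consensus cascade refines
    pharmacophore hits by docking-score thresholds relative to a reference
    ligand and by key binding-residue interaction overlap. MM-PBSA
    binding-free-energy components are aggregated per snapshot and decomposed
    per residue, with RMSD/RMSF trajectory summaries. A synthetic benchmark
    generator plants known feature arrangements, score effects and energy
    distributions so every stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
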