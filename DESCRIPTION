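Package: nanocyp
Title: Nanotube-Protein Interaction Fingerprints and Channel Occlusion Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Toolkit", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds armchair single-walled carbon nanotube models with edge
    carboxylation, reads and writes PDB/GRO structures and multi-model PDB
    trajectories, and computes interaction fingerprints between a nanotube and
    a protein: heavy-atom contacts, hydrogen bonds, salt bridges and
    parallel/T-shaped pi-pi stacking, with per-residue formation ratios.
    Provides a substrate-channel occlusion statistic (per-run blocking onset
    and pooled blocked-time fraction), pairwise Lennard-Jones/Coulomb
    interaction-energy series, Kabsch-superposed C-alpha RMSD series, a
    seeded synthetic-trajectory generator with exact ground truth for
    detector validation, and a config-driven analysis pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
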