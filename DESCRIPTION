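Package: disofold
Title: Order/Disorder Assignment for Protein Structure Ensembles by
    Free-Energy Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns ordered/disordered status to residues of protein
    structure models (decoy sets, NMR-style ensembles) by minimizing a
    simple free energy that balances pairwise interaction energy against
    the configurational entropy of disordered terminal tails and internal
    loops. Provides exhaustive enumeration of terminal-tail assignments, a
    greedy block-flip search for internal loops, ensemble disorder-frequency
    profiles, a prediction-accuracy score with its all-ordered null model,
    repulsive-only re-scoring of pre-designated disordered residues, core
    RMSD and core GDT-TS metrics against a native structure, and a
    synthetic decoy-ensemble generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
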