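Package: rligscore
Title: Coarse-Grained Machine-Learning Scoring of RNA-Small-Molecule Docking Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-based rescoring of RNA-ligand docking poses using a
    coarse-grained representation of both partners: five pseudoatom beads per
    ribonucleotide and typed pharmacophore points (with direction vectors) for
    the ligand.  Interactions within a 10 Angstrom cutoff are described by a
    distance and four angles, and per contact-group (base x RNA bead x
    pharmacophore type) probability models (k-nearest-neighbours or a
    feed-forward network) are trained from positive (near-native) and negative
    (decoy) pose collections.  The total score of a pose is the negative sum of
    interaction probabilities plus a weighted, shifted ligand internal-energy
    term.  Includes symmetry-corrected ligand RMSD, S(X) and SR(X,C) docking
    metrics with Monte-Carlo random baselines, pose clustering and local
    optimisation, and a synthetic-fixture generator so the full
    train-score-evaluate loop runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    cluster,
    nnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
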