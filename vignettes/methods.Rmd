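---
title: "Methods: a coarse-grained statistical potential for RNA-ligand pose rescoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coarse-grained statistical potential for RNA-ligand pose rescoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rligscore)
```

## The model

`rligscore` ranks candidate placements of a small molecule in an RNA
receptor by a knowledge-based score learned from examples of good and bad
poses. The central assumption is that the quality of a pose is captured by
the *geometry of its contacts*: which kinds of RNA pseudoatoms sit near
which kinds of ligand chemical features, at what distances and mutual
orientations.

### Coarse-grained representation

Each ribonucleotide is reduced to at most five beads placed exactly on real
atoms — P and C4' for the backbone, plus three base atoms (N9, C2, C6 for
purines; N1, C2, C4 for pyrimidines). Only canonical A, C, G, U residues are
scored; modified or unknown residues are carried through as unusable. The
base plane is summarised by the normalised cross product of the ordered
base-atom triplet, so the normal's sign is a deterministic function of the
input geometry — training and scoring see the same convention, which is all
that matters for the learned angular preferences.

The ligand is abstracted into six pharmacophore feature types. Donor,
acceptor and charge points coincide with their heavy atom; an aromatic point
sits at the ring centroid; lipophilic atoms are merged per bonded region
into a single point at the contribution-weighted centroid. Aromatic points
take the ring-plane normal as direction; donor directions follow the
attached polar hydrogens; acceptor directions point away from the mean
bonded-neighbour direction as a lone-pair proxy. These two vector rules are
the simplest rotation-equivariant choices consistent with the chemistry;
when hydrogens are absent from the input, donors are inferred from free
valence rather than re-protonating the molecule, because protonation-state
prediction is out of scope and the perception is heavy-atom-based anyway.

Lipophilic contributions use a deliberately small atom-level rule (apolar
carbons and halogens 1.0; carbons bonded to exactly one N/O 0.3; everything
else 0), with both constants exposed as arguments. A finer table would
change where LIPO centroids fall but not the structure of the pipeline.

### Contact descriptors

Every (usable bead, pharmacophore point) pair within the interaction cutoff
— 10 Å by default, the value used throughout training and scoring — yields
five descriptors: the distance *d*; *α*, the angle at the bead between the
bead-to-partner-bead axis and the bead-to-point direction; *β*, between that
axis and the pharmacophore direction; *γ*, between the base-plane normal and
the bead-to-point direction; and *δ*, between the normal and the
pharmacophore direction. The partner-bead table (base beads pair with C4';
C4' with P; P with C4') is a convention: it uses only intra-residue beads so
the axis is defined whenever both backbone beads exist, and it is
configurable because any fixed convention is self-consistent between
training and scoring. Angles are kept in degrees in [0, 180]. Descriptors
whose defining geometry is absent (no partner bead, no plane normal,
undirected feature) are stored as missing and the affected records are
excluded from that group's feature set — fixed per-type schemas, never
sentinel imputation, which would plant artificial structure at the sentinel
value.

### Per-group probability models

Contacts are stratified into the 120 groups of base x bead x feature type,
and each group is modelled independently: interaction preferences of, say, a
donor near a guanine N9 have no reason to transfer to a lipophilic point
near a backbone phosphate. Groups with fewer than 10 positive training
contacts are dropped rather than fitted — at that size any fit is noise —
and scoring simply skips (and counts) their contacts rather than penalising
them, since absence of a model is absence of evidence.

Within a group the pipeline is: rescale each feature to [0, 1] on the
training range; remove label noise with a single Edited-Nearest-Neighbours
pass (k = 3, the common default); balance classes by undersampling the
majority; select hyperparameters by held-out accuracy under
cross-validation; refit on all retained records. ENN runs before balancing,
in that order, so that noise removal sees the full neighbourhood structure.
Folds follow ligand clusters when a cluster map is supplied (k-Medoids on
1 − Tanimoto over hashed path fingerprints of the bond graph), so that
held-out performance measures transfer to chemically different ligands;
without a map, seeded stratified folds are used. Ties in the grid go to the
first configuration, so a selected configuration is never strictly worse
than another evaluated one.

Two classifier families are provided. kNN predicts the positive fraction
among the k nearest stored records, with distance ties broken by stored
record order to keep predictions deterministic. The feed-forward network is
a single-hidden-layer perceptron (via `nnet`) with a logistic output; the
default grid explores hidden sizes 16 and 32 with weight decay 0.01 and at
most 200 epochs. Deeper architectures would require a dependency the
package deliberately avoids; at per-group training sizes a single hidden
layer is an adequate function class, and the archive stores the raw weight
vector so prediction is an explicit, reproducible forward pass.

### The score

For a pose, the RNA-ligand term is minus the sum of model probabilities over
all modelled contacts within the cutoff; more, and more native-like,
contacts make the score more negative. The ligand term is
`(E_GAFF − b) · w` with b = 473.58 and w = 0.1 by default: `b` shifts
typical positive force-field internal energies so that relaxed conformers
contribute negatively, and `w` balances the two terms. The internal energy
is an *input* (an `E_GAFF` pose property or argument), not computed here — a
general force field is a separate concern, and keeping the term pluggable
lets users supply energies from any source. When it is absent the term is
zero with a warning. `w` (and the cutoff and `b`) are user-overridable; the
weight in particular is exposed on the command line.

## Post-processing

Three optional steps mirror common docking practice. Greedy clustering
seeds clusters from the best-scored unassigned pose and joins everything
within a 2 Å symmetry-corrected RMSD of the seed. Centroid averaging
resolves atom correspondence through the symmetry mapping that minimises
each member's RMSD to the seed before averaging coordinates — without this,
symmetric ligands would average into nonsense. Local optimisation is a
deterministic rigid-body coordinate descent (translation step 0.5 Å,
rotation step 10 degrees, step halving, at most 200 score evaluations) that
never increases the score and never deforms the ligand; the move set and
stopping rule are a reconstruction of standard practice, stated here
explicitly because finer details of the original procedure are not fixed by
the published description.

## Evaluation metrics

Symmetry-corrected RMSD is the minimum heavy-atom RMSD over all
element- and bond-order-preserving graph isomorphisms (found with igraph's
VF2), with no re-superposition, since poses live in the receptor frame.
Heavy atoms only is the default because deposited hydrogen positions are
unreliable. S(X) is the best RMSD among the top-X scored poses; SR(X,C)
indicates whether any top-X pose is within C Å (boundary inclusive), and is
averaged over complexes. The random baseline draws X poses uniformly
*without* replacement (with-replacement is available behind a flag),
repeated 100000 times by default; the implementation is a vectorised
key-sorting simulation whose estimate the test suite checks against the
hypergeometric closed form. Score–RMSD association is reported as Spearman,
Pearson and Kendall coefficients with mid-ranked ties; constant inputs are
flagged undefined instead of propagating NaN.

## Synthetic fixtures and what they do (not) show

The generator exists so that training, scoring and evaluation are fully
exercisable without downloads. It emulates the *statistical structure* the
trainer assumes, not real complexes:

* a toy RNA — an idealised single-strand helix (rise 2.81 Å, twist 32
  degrees per residue) with every bead-defining atom present and
  non-collinear base triplets, so every residue coarse-grains to 5 beads
  with a well-defined plane normal;
* hard-coded ligand templates (phenol, n-propylamine, acetate) covering
  aromatic, donor/acceptor, charged and lipophilic perception without any
  perception ambiguity;
* pose sets with planted RMSDs — pure translations of the native placement,
  whose length *is* the symmetry-corrected RMSD, with ten poses in the
  0.1–1.5 Å positive band and eight decoys at 4.5–8 Å, mirroring the
  labelling bands the training data design prescribes;
* class-conditional contact tables: positive distances N(3.0, 0.5²)
  truncated to (0, 10], positive angles normal around α = 90°, β = 45°,
  γ = 60°, δ = 30° with 15° spread (characteristic-geometry values chosen
  once as plausible interaction geometry), negatives uniform (d ~ U(2, 10),
  angles ~ U(0, 180)).

Passing tests on these fixtures demonstrates that the machinery is correct:
representations are faithful and equivariant, the pipeline is deterministic,
planted signal is recovered, and the metrics obey their laws. It does *not*
demonstrate benchmark performance on experimentally determined RNA-ligand
complexes, which requires curated structure sets and external docking
programs and is outside this package's scope.

## Numerical choices and degenerate inputs

* Angles come from `acos` of a clamped normalised dot product; zero-length
  vectors yield missing values with a warning.
* Collinear base triplets give no plane normal (signalled, not thrown);
  residues missing atoms simply have fewer beads — nothing is fabricated.
* Feature scaling of a degenerate (constant) feature maps to 0.
* kNN distance ties break by stored record order; grid-search ties by grid
  order; equal pose scores rank by pose order. All three rules exist to make
  results reproducible to the byte under a fixed seed.
* Average (IUPAC standard) atomic weights implement the 1000 Da mass rule,
  matching the formula-weight convention of structure databases.
* Model archives are plain text (CSV reference sets, JSON weights) with
  per-file and whole-archive checksums; loading verifies both.
* Symmetry mappings beyond a cap (10000) are truncated with a warning; the
  minimum over the enumerated subset is still an upper bound on the true
  symmetry RMSD.

## Problem sizes used in the checks

The shipped checks run the trainer at up to 2000 records per class per
group, the fixture loop on 18-pose complexes over 20 seeds, and Monte-Carlo
baselines at 2 x 10^4–10^5 draws; these sizes give stable statistics for the
properties being tested (e.g. the 4-sigma band of the baseline comparison)
while keeping a full run of the suite in the low minutes on one CPU.

## Known limitations

* The receptor is rigid and water/ions are not modelled.
* The score ranks poses; it is not calibrated to binding free energy.
* Pharmacophore perception is rule-based; tautomers and computed partial
  charges are out of scope (formal charges only).
* The exact lipophilicity table and the donor/acceptor vector definitions of
  the original perception tool behind this class of models are not published
  in detail; the rules here are simple, stated, and configurable, and any
  consistent convention is self-consistent between training and scoring.
* The identity of the "partner" pseudoatom in the angular descriptors is a
  convention (documented above) and may differ from other implementations;
  models trained with one convention must be scored with the same one. This
  is enforced by shipping the convention inside the model archive pipeline.
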