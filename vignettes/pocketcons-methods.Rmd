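---
title: "Energy- and conservation-based binding-site prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy- and conservation-based binding-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pocketcons` predicts protein-ligand binding sites from two signals: the van
der Waals interaction energy a small carbon probe feels near the protein
surface, and the evolutionary conservation of nearby residues. This vignette
is the package's account of the underlying models, the parameters that
matter, the numerical choices, and what the synthetic fixtures do and do not
demonstrate.

## The energy model

A single carbon atom stands in for a ligand fragment. Probes sit on an
axis-aligned grid with 0.5 Å spacing covering the protein bounding box plus
an 8 Å margin; the margin is not part of the published protocol, and 8 Å
was chosen so that surface pockets are fully sampled while the probe count
stays bounded (both are configurable). Each probe is scored with the
Lennard-Jones 6-12 potential against every protein atom within 10 Å (hard
truncation, no switching):

$$E^{van}_{ij} = \sqrt{\varepsilon_i\varepsilon_j}
  \left[\left(\frac{R_i+R_j}{r_{ij}}\right)^{12}
  - 2\left(\frac{R_i+R_j}{r_{ij}}\right)^{6}\right]$$

so the minimum is exactly $-\sqrt{\varepsilon_i\varepsilon_j}$ at
$r = R_i + R_j$. The well depths combine as a geometric mean — the standard
Lorentz–Berthelot-style rule, consistent with each atom carrying its own
$R$ and $\varepsilon$. Parameters are AMBER parm94 nonbonded values, shipped
as an editable text asset together with the atom-name → atom-type map for
the 20 standard residues; the probe defaults to the parm94 aliphatic sp³
carbon (CT: $R = 1.908$ Å, $\varepsilon = 0.1094$ kcal/mol), the closest
single-atom analogue of a methyl probe. This energy is a *ranking device*,
not a binding free energy: no electrostatics, solvation or flexibility.

Atoms with no name mapping (non-standard residues such as MSE) fall back to
element-generic parameters with a warning, or to an error when the fallback
is disabled. Structures are used as supplied: hydrogens are included when
present (an `ignore_hydrogens` flag drops them), and missing side chains
are an input precondition — protonation and side-chain reconstruction are
deliberately outside the package.

## Clustering

Candidate sites are grown by an incremental energy-threshold procedure. The
threshold starts at the minimum probe energy and rises in 0.1 kcal/mol
steps; at each step, probes at or below the threshold become active — one
at a time, in ascending energy with ties broken lexicographically on
position, which makes the outcome independent of input order — and join
every cluster that has a member within 1 Å (boundary inclusive), merging
clusters they bridge. Inter-cluster distance is nearest-member distance.
The procedure ends the moment any cluster reaches `p_num = 500` members
(the reading where the cap ends the whole procedure, rather than freezing
one cluster), and all clusters existing at that instant are returned. Two
consequences worth knowing:

* a probe that bridges two large clusters can push the capped cluster past
  `p_num` in its final step; the cap is a stop condition, not a hard size
  limit;
* threshold steps that would admit no probe are skipped arithmetically;
  this changes nothing observable and keeps degenerate inputs (isolated
  high-energy probes) cheap.

Probes with positive energy are pruned before clustering by default.
Because activation proceeds from the lowest energy upwards, pruning at any
level at or above the final threshold cannot change the result — a property
the test suite checks directly against a literal, quadratic transcription
of the procedure (`brute_force_cluster_oracle()`).

## Conservation

Per-residue conservation is the Jensen-Shannon divergence, base 2, between
a position's amino-acid frequency vector $P$ and a background $Q$:
$C = \tfrac12 KL(P\|M) + \tfrac12 KL(Q\|M)$, $M = (P+Q)/2$, with
$0\log 0 = 0$, so $C \in [0, 1]$. Frequencies come either from the
weighted-observed-percentage block of a PSI-BLAST ASCII PSSM (columns
23–42; the explicit frequency estimate, in preference to back-transformed
log-odds) or from a user-supplied alignment. Running PSI-BLAST itself is
out of scope — the package consumes its output file. The background
defaults to the Robinson-Robinson frequencies associated with BLOSUM62
(shipped as a text asset; a uniform option exists) since the divergence
needs a strictly positive reference. No sequence-window averaging is
applied: the score is plain per-position.

Profile positions map onto structure residues by exact sequence match, by
substring match when the structure resolves fewer residues, or by a global
alignment (Biostrings, BLOSUM62) otherwise; below 90 % identity over the
aligned region the mapping errors out rather than guessing. Structure
residues with no mapped position receive the chain-median score with a
warning.

## The weighted score and ranking

Each probe is rescored as

$$E_i = \sum_{j \,\in\, \text{10 Å}}\left(w_1 E^{van}_{ij} + w_2 C_j
  + w_3 E^{van}_{ij} C_j\right)$$

with defaults $(w_1, w_2, w_3) = (1, -0.05, 9)$. $C_j$ is the conservation
of atom $j$'s residue *if* that residue has any atom within 6 Å of the
probe, and 0 otherwise; the residue's score applies to all of its atoms.
Both conservation-containing terms are gated at 6 Å by default — a nonzero
cross term from atoms at 6–10 Å would contradict the premise that distant
residues should not influence the score — but `gate_cross_term = FALSE`
exposes the alternative reading. Clustering uses the raw energies;
weighting only affects ranking, matching the step order of the protocol.
The score is linear in the weights, so the per-probe component sums are
computed once and any weight setting (including the `weight-grid` utility
and the energy-only mode $w_2 = w_3 = 0$) is a cheap linear combination.

Clusters are ranked by ascending total $E_i$; ties break on lower raw
energy, then on the lexicographically smallest member position. For
multimers, clusters on distinct chains whose chain-stripped contact-residue
sets overlap with Jaccard ≥ 0.7 and whose totals agree within 10 % are
treated as symmetric copies; only the lowest-scoring one stays
representative. Both thresholds are configurable — the published procedure
states the intent ("similar clusters with similar energies") but no
criterion, so these values are this package's own operationalization.

## Evaluation protocols

*Binding space*: a cluster probe overlaps the ligand when it lies within
1.6 Å of a ligand heavy atom; cluster precision is the overlapping
percentage and ≥ 25 % (boundary inclusive) counts as success.
*Binding residues*: residues within 5 Å of any cluster probe are the
predicted set; residues within 4 Å of any ligand heavy atom (unioned over
ligands) are the ground truth; `S_residue` is residue-level precision and
MCC uses the convention 0 when any denominator factor vanishes. Ligands
are selected by the biological-relevance filter: non-water HETATM groups,
single-linkage at 4 Å, at least 10 heavy atoms and at least 70 protein
contacts within 4 Å. For unbound structures a truth table replaces the
ligand route.

## The synthetic fixtures

The generator emits a slab of CA-only glycine pseudo-residues on a 2 Å
lattice (thickness 10 Å, lateral size from `wall_atom_count`), carves a
hemispherical pocket (radius and depth 5 Å by default), and plants a
12-atom pseudo-ligand on a spherical shell 2.7 Å from the cavity surface.
These constants were chosen so the planted ligand passes the
biological-ligand filter with margin (76–93 contacts across seeds); the
generator verifies this and errors on infeasible geometry. Wall atoms carry
a uniform ±0.15 Å jitter controlled by the seed; the cavity centre sits
halfway between lattice sites so the wall shell around the ligand does not
depend on slab-size parity. The homodimer variant appends an exact
translated copy as chain B — translation being the simplest rigid transform
that keeps the two pockets' probe environments bit-comparable. Conservation
files assign each position the profile
$\text{conc}\cdot\delta_{\text{query}} + (1-\text{conc})\cdot Q$ with
`conc = high` (0.95) on pocket-lining residues of conserved chains and
`low` (0.05) elsewhere, emitted both as an integer-percentage PSSM and as a
100-sequence alignment; integer rounding limits their mutual agreement to
about ±0.02 in `C_score`, which is the tolerance the consistency tests use.

What passing on these fixtures shows: the geometry pipeline finds a
concave, energetically favorable cavity; conservation weighting can
overturn a purely energetic ranking (on the slab, the deepest-energy
cluster is a surface crevice belt, *not* the pocket — exactly the failure
mode the weighted score addresses); symmetric multimer sites deduplicate.
What it does not show: performance on real proteins, whose packing,
chemical heterogeneity, structural noise and PSSM quality the fixtures do
not emulate. The published large-scale benchmarks require hundreds of PDB
structures plus database-derived PSSMs and are out of scope here.

## Numerical choices and limitations

* Boundary comparisons (10 Å cutoff, 1 Å linkage, 6 Å gate, 1.6/4/5 Å
  evaluation radii, 25 % thresholds) are all inclusive (≤ / ≥).
* The optimized energy and clustering paths use cell-list spatial indexing
  (C++); both are required by the test suite to agree with literal
  all-pairs/quadratic reference implementations to 1e-9.
* Pair distances of exactly zero (a probe coinciding with an atom) are
  excluded from the energy sum rather than producing infinities; such
  probes are dominated by their clash energy in any case.
* Two geometrically identical pockets tie only up to floating-point noise
  (~1e-12 relative): which copy ranks first is then not meaningful, and
  the dimer tests assert near-equality plus adjacency rather than a
  specific order. Exact ties resolve by the documented tie-break.
* `P_num` (500) trades sensitivity for precision: for ligands much smaller
  than the cap the cluster overfills, which depresses precision — visible
  in the fixtures as rank-1 precision around 83 % rather than 100 %.
* Problem sizes in the tests (fixtures of 700–1500 wall atoms, probe grids
  of 0.2–0.8 million points, oracle comparisons at ≤ 500 probes) were
  picked so the full suite and the acceptance script each run in a few
  minutes on one core.
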