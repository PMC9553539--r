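---
title: "Predicting protein-protein interface residues: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interface residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppisite)
```

## The problem

When two proteins form a complex, only a small fraction of each partner's
surface participates in the contact. Identifying those interface residues
from structure and sequence-derived features is a long-standing problem in
structural bioinformatics: interfaces are chemically unremarkable patches,
no single descriptor separates them from the rest of the surface, and
interface residues are rare — on curated heterocomplex sets roughly 10% of
all residues — so naive classifiers collapse onto the majority class.

`ppisite` implements a complete pipeline for this problem: structure-derived
labeling, a 40-component per-residue encoding, three ways of building
classification samples, mutual-information feature ranking (mRMR),
incremental feature selection (IFS) under cross-validated random forests,
and repeated balanced undersampling for the class imbalance.

## Ground-truth labeling from structure

Labels come from solvent accessibility. Per-residue accessible surface
area (ASA) is computed by the Shrake–Rupley method: each heavy atom is
surrounded by a deterministic Fibonacci lattice of test points at radius
(vdW + probe); the fraction of points not buried inside any neighbouring
expanded sphere, times the expanded-sphere area, is the atom's ASA, and a
residue's ASA is the sum over its atoms. Defaults: probe 1.4 Å (water),
960 points per atom, united-atom vdW radii (C 1.70, N 1.55, O 1.52,
S 1.80 Å; hydrogens ignored). The lattice is deterministic, so ASA values
are exactly reproducible; at 960 points per-residue values agree with a
10,000-point evaluation to well within 2% on our fixtures.

Two rules then define the classes:

* **Surface**: relative accessibility RASA = ASA / maxASA(aa) strictly
  greater than 0.25, with maxASA the Tien et al. (2013) theoretical
  maxima. RASA is evaluated on the *monomer* (the chain extracted alone),
  since interface residues are buried in the complex by definition.
* **Interface**: a surface residue whose monomer ASA (MASA) exceeds its
  complex ASA (CASA) by at least 1 Å². Interface status structurally
  implies surface status; non-surface residues are never interface.

`label_structure()` runs both: CASA on the full assembly, MASA by
re-running ASA on each chain alone, then the two rules.

## The 40-component residue encoding

Each residue is a fixed-order concatenation of five blocks:

| block | width | content |
|---|---|---|
| Atchley factors | 5 | polarity, secondary-structure propensity, size, codon composition, charge |
| PSSM | 20 | PSI-BLAST log-odds conservation scores (read from ASCII profiles, used raw) |
| secondary structure | 3 | one-hot E/H/C (strand 100, helix 010, other 001) |
| disorder | 1 | per-residue disorder score in [0, 1] |
| 3D structural | 11 | ASA, RASA, depth/protrusion-style descriptors, hydrophobicity, surface geometry |

The structural block is a named-column table of configurable width
(default 11). The literature on such descriptor sets enumerates fewer
distinct names than the count it quotes; we therefore treat the block as a
configurable table — ASA, RASA and Kyte–Doolittle hydrophobicity can be
computed natively, the remaining depth/protrusion/curvature columns are
consumed from external descriptor tables (TSV) rather than recomputed.
The padding symbol `X` encodes as all zeros in every block, including the
secondary-structure one-hot (whose bits otherwise sum to exactly 1).

## Sample construction

Only surface residues become sample centers; the sample count always
equals the surface-residue count.

* **Single residue**: the 40-vector itself.
* **Sliding window**: the center plus *n* residues up- and downstream in
  sequence (window length N = 2n+1, 1 ≤ n ≤ 19), chain termini padded
  with `X`; dimension N × 40. The label is the center's label.
* **Spatial patch**: the center plus its m−1 nearest residues by
  Euclidean distance between representative atoms (Cα, else centroid),
  10 ≤ m ≤ 25. Patches may cross chain boundaries — spatial neighbours
  are spatial — and members need not be surface residues; only centers
  must be. Members are ordered center first, then ascending distance,
  ties broken by (chain, residue number), so the column layout is
  deterministic.

## mRMR ranking

Relevance and redundancy are both measured by plug-in mutual information
in bits on discretized features. Discretization is the 3-level rule of the
classic mRMR program: bins at mean ± α·sd (α = 1 by default). Two
numerical choices matter and are worth stating precisely:

* the sd is the *population* standard deviation, and the thresholds are
  inclusive. With the sample sd, a balanced 0/1 feature (sd ≈ 0.5006)
  would bracket both values into the middle bin and lose all its
  information; with the population sd (exactly 0.5) and inclusive
  boundaries it discretizes to −1/+1 as intended. For continuous data
  the two conventions differ only on a measure-zero boundary set.
* logarithms are base 2, so relevance of a feature identical to balanced
  binary labels is exactly 1 bit.

The greedy ranking picks argmax relevance first, then repeatedly maximizes
D − R (MID, the default, matching the difference form of the criterion) or
D / R (MIQ, selectable; R guarded below by 10⁻¹²). Ties go to the lower
feature index, making the permutation deterministic. Every pick's
criterion provably dominates all unchosen candidates at that step — the
test suite certifies this against a brute-force re-evaluation and checks
exact order agreement with an independent greedy implementation.

For window/patch samples, `mrmr_rank_samples()` ranks the per-residue
*catalog* (the 40 features) on the center residue's block. This is the
reading under which "the first i of 40 features" is consistent with
440-dimensional window samples.

## IFS and the random-forest evaluator

Incremental feature selection walks prefixes of the ranking: for each i,
the first i catalog features — each expanded to its column at every
window/patch position — are evaluated by a cross-validated random forest,
and the prefix maximizing MCC wins (ties toward the smaller subset;
undefined MCC is propagated as `NA` and never wins silently).

The forest is delegated to `ranger` (seeded, single-threaded, majority
vote; default 197 trees, the tuned forest size of the tree-count sweep).
Cross-validation uses stratified, seeded folds at the sample level (the
source data give no per-complex grouping rule; complex-level leakage is a
known limitation, see below). Per-fold confusion counts are pooled into
one table and the five measures — sensitivity, precision, specificity,
accuracy, MCC — are computed once on the pooled counts, which stays
well-defined when a small fold lacks a class.

Class imbalance is handled by repeated balanced undersampling: each round
keeps all positives plus an equal-sized seeded draw of negatives (without
replacement within a round), cross-validates the balanced subset, and the
final result is the arithmetic mean of each metric across rounds (100 by
default), matching the convention of averaging results rather than pooling
counts across rounds.

## What the synthetic data emulates

`simulate_feature_dataset()` plants exactly the statistical structure the
pipeline assumes: informative features are N(0,1) vs N(effect, 1) between
classes; redundant features are jittered copies of an informative parent;
noise features are label-independent; and the positive fraction defaults
to 0.10, the interface-residue imbalance of curated heterocomplex sets.
Class counts are fixed by rounding (not Bernoulli draws) so
balanced-sampling tests are deterministic in shape.
`simulate_dimer()` builds toy two-chain structures (linear or ideal-helix
backbones with N/CA/C/O/CB atoms) in which the partner chain runs parallel
at ~5 Å over half the chain length, so a contiguous run of residues
verifiably loses ≥ 1 Å² of accessibility on complexation while the rest
does not.

What the generators do **not** emulate: real side-chain packing and
rotamer geometry, sequence-profile realism of PSSMs, spatial correlation
of features along the chain, and homology between samples. Passing tests
therefore demonstrate that the machinery is correct and recovers planted
signal under the stated conditions — not that the predictor reaches any
particular accuracy on real complexes, which depends on external feature
generators and curated structure sets.

## Problem sizes used in the checks

The Monte-Carlo checks run at sizes chosen to make their statistical
claims sharp while remaining desk-scale: feature-recovery uses 100 draws
of n = 2000 samples (3 informative features at effect 2 sd vs 7 noise);
IFS recovery uses 100 draws of n = 500 balanced samples (5 informative +
7 noise, 64-tree forests, 3-fold CV), asserting the MCC-optimal prefix
lands in [5, 12]; the imbalance check uses n = 1100 at 10:1 with 100
balanced rounds, asserting balanced sensitivity strictly exceeds raw
sensitivity on the same seeds. These sizes are the package's own choices
where the underlying protocol fixes the design (counts, effects,
acceptance windows) but not n, k or forest size.

## Known limitations

* Secondary structure, disorder and the depth/protrusion descriptors are
  consumed as input tracks; the external predictors that produce them are
  out of scope, as is running PSI-BLAST.
* ASA uses Shrake–Rupley with united-atom radii, not the hydrogen-bond
  based DSSP machinery; absolute ASA values differ slightly between
  engines, which is why the surface threshold applies to *relative* ASA.
* Sample-level cross-validation can leak homologous residues between
  folds on real data; per-complex grouping is not implemented.
* The mutual-information estimator is the plug-in estimate on 3-level
  discretized features; continuous (e.g. Kraskov) estimators are out of
  scope.
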