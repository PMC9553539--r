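# ppisite

Structure-based prediction of protein–protein interaction (PPI) interface
residues, for structural bioinformaticians who have a complex (or a set of
chains plus feature tracks) and want to know which surface residues form
the binding site.

## What it implements

**Labeling.** Per-residue solvent-accessible surface area (ASA) by the
Shrake–Rupley method (probe 1.4 Å, deterministic Fibonacci point lattice,
united-atom vdW radii). A residue is a *surface* residue when its relative
accessibility RASA = ASA / maxASA(aa) > 25% on the isolated chain, and an
*interface* residue when complex formation buries at least 1 Å² of it:
MASA − CASA ≥ 1, where MASA/CASA are the monomer/complex ASA.

**Encoding.** Each residue becomes a 40-component vector:
5 Atchley factors | 20 PSSM conservation scores (PSI-BLAST ASCII profiles)
| 3-bit E/H/C secondary-structure one-hot | 1 disorder score | an
11-column 3D structural descriptor block. Samples are built per surface
residue as a single residue, a sliding window of N = 2n+1 sequence
neighbours (X-padded at termini), or a spatial patch of the m−1 nearest
residues in 3D.

**Selection and evaluation.** Features are ranked by minimum-redundancy
maximum-relevance (mRMR) with plug-in mutual information in bits on
3-level discretized features, greedy criterion

    max_{f in candidates}  I(f; c) − (1/m) Σ_{s in selected} I(f; s)

(difference form MID; quotient form MIQ selectable). Incremental feature
selection (IFS) then evaluates every ranking prefix with a cross-validated
random forest (`ranger`, 197 trees by default, stratified seeded k-fold,
pooled confusion counts) and keeps the prefix with maximal Matthews
correlation coefficient. The ~10:1 interface class imbalance is handled by
repeated balanced undersampling: 100 rounds of all positives plus an
equal-sized negative draw, metrics averaged across rounds.

A synthetic-data module (`simulate_feature_dataset()`, `simulate_dimer()`)
generates feature tables with planted informative/redundant/noise
structure and toy dimer structures with a planted contact region, so the
whole pipeline is testable offline.

## Worked example

```r
library(ppisite)

## label a (toy) dimer: which residues lose >= 1 A^2 on complexation?
d   <- simulate_dimer(n_residues = 10, seed = 1)
lab <- label_structure(d$structure)
head(lab[, c("chain","resnum","aa","rasa","masa","casa","is_surface","is_interface")], 4)
#>   chain resnum aa  rasa  masa  casa is_surface is_interface
#> 1     A      1  D 0.818 157.9 157.9       TRUE        FALSE
#> 2     A      2  E 0.445  99.3  99.3       TRUE        FALSE
#> 3     A      3  A 0.770  99.3  99.3       TRUE        FALSE
#> 4     A      4  R 0.362  99.3  99.3       TRUE        FALSE
sum(lab$is_interface)   # 12 of 20 residues sit in the planted contact run

## rank planted features, pick the MCC-optimal prefix, evaluate balanced
sim <- simulate_feature_dataset(1100, n_informative = 5, n_noise = 5,
                                effect_size = 1, positive_fraction = 1/11,
                                seed = 1)
rk <- mrmr_rank(sim$X, sim$y)
head(as.data.frame(rk), 3)
#>   rank feature  name criterion relevance redundancy
#> 1    1       3 inf03    0.0624    0.0624    0.00000
#> 2    2       2 inf02    0.0369    0.0450    0.00819
#> 3    3       5 inf05    0.0315    0.0375    0.00605

incremental_feature_selection(rk, sim$X, sim$y, n_trees = 100, k = 3, seed = 1)
#> ppi_ifs: curve over 10 subset sizes; optimal i = 5 (MCC = 0.5491)

bal <- balanced_ensemble_evaluate(sim$X, sim$y, n_trees = 100, k = 3,
                                  repeats = 20, seed = 1)
round(bal$metrics, 3)
#> sensitivity   precision specificity    accuracy         mcc
#>       0.826       0.833       0.834       0.830       0.660
```

The ranking puts all five planted informative features ahead of the noise
(the `criterion` column is relevance minus mean redundancy, in bits); IFS
finds that exactly those five features maximize MCC; and balanced
undersampling lifts sensitivity far above what the raw 10:1 data yield
(~0.3) at a comparable MCC.

A command-line wrapper with subcommands `label`, `featurize`, `rank`,
`ifs`, `evaluate`, `simulate` is installed at `exec/ppisite` (see
`?ppi_cli`).

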