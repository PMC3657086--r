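---
title: "Methods: the QSAR model matrix, its splits, descriptors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the QSAR model matrix, its splits, descriptors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`qsarmatrix` automates the mechanical portion of QSAR model building —
preparation, splitting, descriptor computation, fitting, validation and
publication — while deliberately refusing to choose a model for the
user. This vignette documents the methods, the tunable parameters and
the design decisions that were genuinely open, so that a modeller can
judge what the package computes and what its tests do and do not
demonstrate.

## The workflow and its assumptions

A project moves through six stages: prepare, split, descriptors, build,
validate, publish. Two assumptions run through all of them:

1. **Determinism.** Every stochastic step takes a seed, and per-model
   seeds are derived by hashing the master seed with the model's
   provenance triple. Re-running any stage with the same inputs
   reproduces its outputs exactly; the published-bundle round trip
   (raw structures in, training predictions out, bit-identical) is a
   direct test of this.
2. **Failures are data.** A learner exception in one cell of the model
   matrix produces a `failed` result with the captured reason; it never
   aborts the run or perturbs another cell. Likewise records that fail
   standardisation or descriptor computation are excluded with a
   logged, per-record reason.

## Chemistry preparation

Standardisation applies an ordered rule list and records it, with any
fitted constants, in the dataset's `prep_spec`; publication copies that
spec into the bundle so predictions replay identical preparation.

* **Desalting** keeps the fragment with the most heavy atoms; ties
  break by descending molecular weight, then ascending canonical
  SMILES. Single-atom ionic or solvent-like fragments are never
  selected, so a pure ion pair ("[Na+].[Cl-]") vanishes and the record
  is excluded with a reason.
* **Neutralisation** is a fixed, documented rule list: O⁻/S⁻ are
  protonated (carboxylates, alkoxides, thiolates) except when part of a
  nitro or N-oxide group, and ammonium-type N⁺ carrying at least one
  hydrogen is deprotonated. Quaternary ammonium is untouched. This is a
  pragmatic stand-in for a proprietary business-rule set; it is applied
  textually to SMILES tokens and always followed by re-canonicalisation,
  so only the canonical output matters.
* **Canonicalisation** delegates to OpenBabel's canonical SMILES.

Response preparation supports `log10` (strictly positive responses
required; violations name the offending record), `unit_variance`
(centre/scale fitted on the data and stored so replay on new data uses
the *training* constants) and categorisation by explicit map or by
strictly increasing thresholds. Threshold boundaries go to the upper
class: intervals are half-open, lower-inclusive at the bottom bin.

## Descriptor blocks

Five blocks, computed on the heavy-atom molecular graph built from the
standardised structure:

| block | size | content |
|---|---|---|
| Molprops | 19 | ALogP, molecular weight, and 17 counts |
| Chi | 12 | χ⁰, χ¹, χ², χ³ path, χ³ cluster, χ⁴ path; simple + valence |
| Estate | 161 | E-state sums and counts over a 79-type alphabet + 3 summaries |
| ECFP6 | 1 | circular fingerprint, radius 3, structural invariants |
| FCFP4 | 1 | circular fingerprint, radius 2, functional-class invariants |

**Molprops.** ALogP is an atomic-contribution lipophilicity estimate
(OpenBabel's logP model; the column name follows the field's
convention). The hydrogen-bond counts come in three conventions each
(pattern-based, count-based, and Lipinski N/O arithmetic) because
different downstream rules expect different conventions. Ring-topology
counts (aromatic rings, bridgehead atoms, bridge bonds, spiro atoms)
come from smallest-ring perception on the graph; stereo counts are read
from the canonical SMILES stereo marks. Where the originating
platform's exact count definitions are proprietary, the definitions
here are fixed and documented; the *names* are kept so models transfer
conceptually.

**Chi.** Simple indices use heavy-atom degrees δ; valence indices use
Kier–Hall valence deltas δᵥ = (Zᵥ − h)/(Z − Zᵥ − 1) for higher-row
atoms and Zᵥ − h for second-row atoms. Order-3 cluster terms sum over
all 3-subsets of neighbours of centres with degree ≥ 3; paths are
enumerated once each.

**E-state.** Intrinsic states I = ((2/N)²·δᵥ + 1)/δ are perturbed by
(Iᵢ − Iⱼ)/r² over all pairs (r = topological distance + 1); perturbation
antisymmetry guarantees ΣS = ΣI, which the tests assert. Atom E-states
are aggregated as per-type sums and counts over a fixed 79-entry
alphabet (bond-pattern prefix + element + hydrogen count, in the
classical naming style) plus total/max/min, giving exactly 161 columns.
Types for elements outside the organic parser are inventory
placeholders that never fire; isolated heavy atoms use the
hydrogen-inclusive convention δ = 1.

**Fingerprints.** Morgan iteration over sorted (bond-order, neighbour
identifier) lists with a deterministic 32-bit mixing hash. ECFP6 starts
from structural invariants (atomic number, degree, hydrogen count,
charge, aromaticity); FCFP4 from six functional-class flags (donor,
acceptor, positive, negative, aromatic, halogen). The raw identifier
multiset is kept for Tanimoto similarity and sparse learners; a folded
0/1 expansion of configurable width feeds the numeric learners.
*Fold width* defaults to 1024 columns; it is the one descriptor
parameter with a real accuracy/cost trade-off, and the synthetic study
below uses 256 (see "Problem sizes").

In subset accounting each fingerprint block counts as **one**
descriptor (matching how descriptor inventories in this field count a
fingerprint as a single descriptor), so the union subset over all five
blocks counts 12 + 1 + 161 + 1 + 19 = 194.

## Splits

Seven standard splits: `Rand50/75` (uniform sampling of
`round(n·fraction)`), `IndOpt50/75` and `RPC50/75` (cluster-driven, see
below), plus one predefined split loaded from a two-column file.
A stratified split (quantile bins, per-bin fraction within one record
of target, undersized bins merged with a warning) is available for
building predefined splits and replay.

**Clustering** is sphere exclusion (Butina-style): the unassigned
record with the most unassigned neighbours within the similarity
threshold becomes a centroid and claims them; ties break to the
earliest record. Neighbour counts are recomputed among unassigned
records at every step, which is the variant the package's brute-force
oracle also implements. Default: Tanimoto ≥ 0.7 on raw ECFP6
identifier sets; property-space clustering (similarity 1/(1+d) over
unit-scaled Molprops) is available.

**Independent clusters (optimized)** assigns whole clusters to the test
side minimising |achieved − target| test fraction. For ≤ 16 clusters
the optimum is found by exhaustive enumeration (the subset-sum optimum
a greedy pass cannot guarantee); beyond that, greedy descending-size
assignment with single-cluster swap improvement. Ties between equally
good subsets break by seed-shuffled enumeration order. This makes the
test set deliberately dissimilar from training — an approximate
leave-class-out, the pessimistic end of the difficulty scale.

**Random per cluster** samples `round(size·fraction)` inside every
cluster of size ≥ 2. Singleton clusters are assigned by a
Bernoulli(fraction) draw — a documented choice where the alternative
(always train) would bias the achieved fraction upward on
singleton-heavy data.

**Split diagnostics** embed the 1 − Tanimoto distance matrix by
classical (metric) MDS (`cmdscale`), report a normalised stress value,
and summarise train/test overlap as each test record's
nearest-training-neighbour similarity. Sign and rotation of the
embedding are not canonicalised; tests compare against an
eigendecomposition oracle up to orthogonal transformation. An
all-identical distance matrix yields zero coordinates with a warning.

## Learners

Seven learners with declared capabilities and defaults — defaults are
*declared, not tuned*:

| learner | endpoint | implementation | non-library defaults |
|---|---|---|---|
| pp_bayes | categorical | authored Laplacian-modified naive Bayes | K = 1 |
| rp_tree | categorical | rpart | — |
| rp_forest | categorical | randomForest | 100 trees |
| nn | both | nnet | size 3, decay 0.01, maxit 100 |
| svm | both | e1071, RBF | — |
| pls_nipals / pls_simpls | continuous | authored PLS1 | ncomp by 5-fold CV, cap 10 |

The Bayes scorer binarises features at the training median (fingerprint
bits are already 0/1) and weights each present feature by
log((A_f + 1)/((N_f + 1/p)·p)), A_f = positives with the feature,
N_f = records with it, p = training positive fraction; the decision
threshold maximises Youden's J on training scores. The two PLS learners
are independent algorithms (NIPALS and SIMPLS) that agree numerically
for a univariate response — a built-in cross-check — and reduce to
ordinary least squares at full rank, which the tests assert against
`lm`. Inputs to nn and svm are range-scaled to [0,1] on training
ranges (constant columns pinned to 0) so zero-variance descriptors
cannot abort a fit. Categorical model building requires binary labels;
multi-class responses should be binarised during preparation.

## Validation and triage

ROC uses a descending threshold sweep with tied scores grouped into a
single step and trapezoidal area — exactly pairwise concordance with
ties counted ½, which the acceptance tests verify against a brute-force
oracle at 10⁻¹² on 100 fuzzed instances. R² is the coefficient of
determination against the truth mean (not squared Pearson correlation).
REC curves default to 100 evenly spaced tolerances from 0 to the
maximum absolute error, with the area normalised by the grid span so
models on different response scales are comparable. Undefined rates
(a class absent from the truth) are reported as `NA`, never silently 0.
Y-scrambling permutes the *training* responses only, refits, and
records the test statistic; the observed statistic is compared against
the scrambled distribution's mean, spread and maximum.

The triage table is a plain tibble — one row per attempted model with
the provenance triple and all statistics — so the full dplyr vocabulary
applies; `triage()` additionally guarantees stable sorting and
non-mutating filters, and `triage_breakdown()` provides the
counts-by-learner/split/subset views whose totals always equal the
selection size.

## The synthetic data generator

The generator assembles molecules from an embedded fragment grammar
(8 mono-, 4 di- and 2 tri-substituted scaffolds × 30 substituents;
aromatic and aliphatic, N/O/S heterocycles included). Classification
sets plant a sulfonamide pharmacophore (–S(=O)(=O)N) in a
`class_balance` fraction of records; the label is determined by its
presence and then flipped with probability `noise` (default 0.1,
roughly an assay misclassification rate). Regression sets compute the
response as 1.2·logP + 0.8·ringcount + N(0, sd); with sd equal to the
signal's own standard deviation the best achievable R² is about 0.5 by
variance decomposition, which the tests confirm. A `salt_fraction`
(default 0.1) of records is emitted as salt forms — amine
hydrochlorides where the chemistry allows, HCl companions otherwise —
so desalting and neutralisation are exercised in-pipeline.

What the generator does *not* emulate: real structure–activity
landscapes (activity cliffs, scaffold hopping), assay heteroscedastic
noise, and — importantly — the dense analogue-series structure of
lead-optimisation datasets. The grammar's pairwise ECFP6 Tanimoto
similarities are sparse (90th percentile ≈ 0.2), so the clustered study
conditions use a similarity threshold of **0.35**, chosen once from
that similarity distribution at fixture-design time, to obtain
multi-member clusters; the package default of 0.7 reflects real
datasets where near-analogues are abundant. Consequently, a passing
test suite demonstrates the machinery — signal recovery, split
difficulty ordering, chance-correlation baselines — not performance on
any real endpoint.

## Problem sizes

The end-to-end synthetic study (tests and acceptance script) uses 300
records, the full 350-model categorical matrix, fingerprints folded to
256 columns, 20 Y-scrambling permutations, and 20 seeds for the
split-difficulty contrasts. These sizes were chosen as the smallest at
which the studied effects are stable across seeds; the fold width of
256 (vs the 1024 default) mainly trims the neural-network fits, whose
cost grows linearly in input width while the planted signal is already
fully expressible at 256 columns.

## Numerical choices and degenerate inputs

* Hashing is a 32-bit FNV-style mix kept exact in doubles and reduced
  mod 2³¹, so identifiers and derived seeds are platform-stable R
  integers.
* `round()` (banker's rounding) decides train-set sizes; split
  constructors clamp so neither side is ever empty and raise errors on
  n = 1 or out-of-range fractions.
* Subset-sum ties in the independent-cluster split, and equal neighbour
  counts in clustering, break deterministically (seed-shuffled order;
  earliest index).
* PLS stops early when residual covariance falls below 10⁻¹² and
  reports "no descriptor variance" on constant matrices — surfacing as
  a failed matrix cell, per the failure-isolation contract.
* Records whose standardised structure cannot be re-parsed are excluded
  from descriptor matrices with a reason; matrices therefore contain no
  missing values by construction.

## Known limitations

* Tautomer canonicalisation, stereochemistry repair and 3D descriptors
  are out of scope; stereo information only enters through two count
  descriptors.
* The aromaticity model is a simplified Hückel treatment of 5/6-rings
  adequate for common heteroaromatics; exotic ring systems may be
  perceived as non-aromatic.
* Applicability reporting is limited to per-column training-range
  checks; no Mahalanobis-type domain metrics are computed.
* Ensemble/data-fusion modelling over the matrix is intentionally
  absent — the matrix is a pool for human selection, not an ensemble.
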