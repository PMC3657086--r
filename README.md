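# qsarmatrix

Automated QSAR model-matrix construction, triage and publication in R.

## The problem

Building a quantitative structure–activity relationship (QSAR) model is
never one decision: the modeller chooses how to standardise the
chemistry, how to split the data into training and test sets, which
descriptors to compute, and which statistical learner to fit — and no
combination is best for every endpoint. `qsarmatrix` automates the
mechanical part of that exploration for drug-discovery and toxicology
modellers: it builds the **full cartesian matrix of models** over

```
splits  ×  descriptor subsets  ×  learners
```

with *no competitive selection* — every model is kept, with its train
and test statistics, and the choice is left to the modeller, guided by
sortable triage tables, train-versus-test summary plots, ROC/REC curve
families, Y-scrambling baselines and chemical-space split diagnostics.
A chosen model is *published* as a self-contained bundle that replays
every data-preparation step at prediction time.

In the standard configuration — seven splits (random, independent
clusters optimized, random per cluster at 50 % and 75 % training
fractions, plus one predefined split), ten descriptor subsets over five
blocks (Molprops 19, Chi 12, Estate 161, ECFP6, FCFP4; 194 descriptors
in the union subset), and the capability-filtered learner registry
(naive Bayes, recursive-partitioning tree and forest, neural network,
SVM for categorical endpoints; neural network, SVM and two PLS variants
for continuous ones) — the matrix spans **350 models for a categorical
endpoint and 280 for a continuous one**.

Key methodological pieces:

* **Sphere-exclusion (Butina) clustering** on fingerprint Tanimoto
  similarity drives two splits of opposite difficulty: the
  *independent-clusters* split holds out whole clusters (test chemistry
  deliberately dissimilar from training), while *random-per-cluster*
  samples inside every cluster (test chemistry similar to training).
  Classical MDS maps of the fingerprint distance matrix visualise the
  difference, and the package's statistical tests confirm the expected
  direction: whole-cluster test sets score no better.
* **Descriptor engines** computed on the heavy-atom molecular graph:
  19 interpretable molecular properties, Kier–Hall chi connectivity
  indices (χ⁰…χ⁴ path/cluster, simple and valence), electrotopological
  state (E-state) sums and counts over a fixed atom-type alphabet, and
  Morgan-style ECFP6/FCFP4 circular fingerprints with configurable
  folding. Chemistry standardisation (desalting, neutralisation,
  canonical SMILES) is handled through OpenBabel (ChemmineR/ChemmineOB).
* **Validation**: confusion rates, tie-aware trapezoidal ROC AUC,
  coefficient-of-determination R², RMSE, regression error
  characteristic (REC) curves, external validation sets, and
  Y-scrambling (refitting after permuting training responses) to
  estimate the chance-correlation baseline.
* **Publication**: a bundle freezes the preparation spec (with fitted
  constants), descriptor configuration, fitted model, statistics and
  per-column training ranges; predictions on raw structures (salt forms
  included) replay the identical pipeline bit-for-bit and warn when a
  descriptor falls outside the training range.

## Worked example

```r
library(qsarmatrix)

# synthetic dataset with a planted sulfonamide pharmacophore (10% label noise)
ds   <- standardize(generate_classification_set(300, seed = 17, noise = 0.1))
desc <- compute_descriptors(ds, fold_width = 256)
cl   <- cluster_molecules(ds, similarity_threshold = 0.35, descriptors = desc)
splits  <- standard_splits(ds, seed = 17, cluster_of = cl, descriptors = desc)
subsets <- default_subsets()

proj  <- project_set_stages(qsar_project(), ds, splits, desc, subsets)
specs <- enumerate_models(splits, subsets, learner_registry()$name, "categorical")
nrow(specs)
#> [1] 300            # 6 splits x 10 subsets x 5 categorical learners

mm <- run_matrix(proj, specs, seed = 19)
mm
#> <qsar_model_matrix> 300 models attempted, 300 built, 0 failed

tbl <- triage(mm, sort_keys = "test_roc_auc")
head(tbl[, c("split_label", "subset_label", "learner_name", "test_roc_auc")], 3)
#>   split_label   subset_label learner_name test_roc_auc
#> 1      Rand75 ECFP6_Molprops           nn    0.9614826
#> 2      Rand75          ECFP6    rp_forest    0.9516715
#> 3      Rand75          ECFP6           nn    0.9469477
```

The triage table is the spreadsheet view: one row per model with the
provenance triple and all statistics, sortable and filterable without
mutating the results; `autoplot(tbl)` draws the test-versus-train
summary plot, `plot_roc(mm)` the ROC family, and
`autoplot(analyze_split(ds, splits$IndOpt75, descriptors = desc))` the
chemical-space split map. `y_scramble()` on a chosen configuration
returns the scrambled-AUC distribution (expected ≈ 0.5); `publish()`
then freezes the model and `predict(bundle, structures)` scores raw
SMILES with full preparation replay.

A thin command-line front end over these functions ships in
`inst/cli/qsarmatrix.R` (`fixtures`, `prepare`, `split`, `descriptors`,
`build`, `validate`, `publish`, `predict`).

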