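# buccalclocks

Methylation-based predictors for buccal (cheek swab) samples. Starting
from a sample × CpG beta-value matrix, the package builds:

* **classifiers** (random forests) for smoking status and race/ethnicity,
* **regressors** (feed-forward neural networks) for weekly alcohol intake
  (on a 0–1 health score), body mass index, and chronological age — i.e.
  first-generation epigenetic aging clocks,
* **biology-masked explainable aging clocks** whose hidden layers are
  annotated genes and curated gene sets (pathways or transcription-factor
  target sets), so each predicted age decomposes into named gene-set
  neuron activations,

together with the surrounding methodology: beta↔M transforms,
correlation-based CpG selection, exhaustive random-forest grid search with
5-fold cross-validation, impurity and path-integral feature attribution,
gene-set and genomic-feature overrepresentation analysis (hypergeometric
tests, Benjamini–Hochberg FDR), PCA/silhouette batch-effect screening,
reference-based cell-fraction estimation, and linear association models
for age acceleration. A synthetic-cohort generator with planted,
configurable signal makes the entire pipeline testable end to end without
access to any real cohort.

## The models in brief

Beta values `β ∈ [0,1]` are transformed to M values
`M = log2(β / (1 − β))` after clipping `β` into `[1e-5, 1 − 1e-5]`;
all modeling happens on the M scale. For each target, CpGs are ranked by
Pearson correlation `r(CpG, target)` and the top k (by |r|) become the
model inputs; for race/ethnicity the feature set is the union of the
top k per one-hot class indicator.

Classifiers are random forests tuned by exhaustive grid search over
forest size × tree depth, each cell scored by mean accuracy over a fixed
stratified 5-fold split; performance is always reported on out-of-fold
(OOF) predictions, and the final model is refit on all data.

Regressors are feed-forward networks (0–3 hidden ReLU layers) trained
full-batch with Adam under mean-squared-error loss and 5-fold CV. The
explainable clock restricts connectivity with binary masks: CpG→gene
(array annotation) and gene→gene-set (GMT collections), with a linear
gene-set→age readout. Masked weights and their gradients are multiplied
by the mask after every optimizer step, so they are exactly zero
throughout training; a fully connected control with identical layer
widths quantifies the accuracy cost of the biology-guided sparsity.

Age acceleration (delta age) is `predicted age − chronological age`, and
is screened for lifestyle/health associations by ordinary least squares
with BH-adjusted coefficient p-values.

## Worked example

```r
library(buccalclocks)

# simulate a cohort of 500 buccal methylomes with age signal at 300 CpGs
cfg <- synth_config(seed = 1)
ann <- generate_annotation(cfg)
cohort <- generate_cohort(cfg, ann)
m <- beta_to_m(cohort$beta)

# select the 1,000 CpGs most correlated with age and train the clock
age <- cohort$metadata$age
features <- select_top_k(cpg_correlations(m, age, "age"), 1000)
clock <- train_ffnn_cv(unclass(m)[, as.character(features)], age,
                       arch_spec("custom", c(64L, 16L)),
                       train_config(lr = 0.01, epochs = 200, seed = 1))
clock$metrics
#> r = 0.9940 (p = 0), MAE = 1.9850, RMSE = 2.5041 (n = 500)

# age acceleration of the first samples
head(round(delta_age(clock$oof, age), 1))
#> [1] -0.9  3.1  2.3  0.8 -4.2 -2.3
```

The printed metrics are out-of-fold: each sample's age was predicted by
the fold model that never saw it. `r` is the Pearson correlation between
predicted and true age, MAE/RMSE are in years. The `train_config()`
defaults hold the reference protocol (Adam at lr 1e-6 for 2,500 epochs);
the example uses the faster desk-scale protocol, which the fit records in
its provenance.

The same pattern drives the other predictors (`train_rf_cv()` for
smoking/ethnicity, `scale_alcohol()` + `train_ffnn_cv()` for alcohol) and
the explainable clock (`build_masks()` + `train_masked_ffnn()`, then
`top_weighted_sets()` and `pathway_activations()` to read out the
gene-set layer). See the methods vignette (`vignettes/methods.Rmd`) for
the full tour and the modeling rationale.

A thin command-line front end over the same functions lives at
`inst/cli/buccalclocks.R`:

```sh
Rscript inst/cli/buccalclocks.R synth --out-dir data --seed 1
Rscript inst/cli/buccalclocks.R classify --target smoking \
    --beta data/beta.tsv --metadata data/metadata.csv --out-dir out
```

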