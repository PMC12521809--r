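---
title: "Buccal methylome predictors: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Buccal methylome predictors: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buccalclocks)
```

This vignette is the package's own account of its methodology: the models
it fits, the assumptions behind them, the parameters that matter, the
numerical choices that were genuinely open, and what the synthetic-data
tests do and do not demonstrate about real cohorts.

## Working scale: beta versus M

A CpG's beta value is the methylated fraction of signal at that site, in
[0, 1]. All modeling here happens on the M scale,
$M = \log_2\!\big(\beta / (1-\beta)\big)$, with $\beta$ clipped into
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-5}$, to avoid
infinities. The log-odds transform stretches the compressed regions near
0 and 1, where biologically meaningful changes are numerically tiny in
beta units; the clip bounds every M value by
$|M| \le \log_2((1-\varepsilon)/\varepsilon) \approx 16.61$.
`beta_to_m()` / `m_to_beta()` are exact inverses away from the clip
bounds, a property the test suite checks to 1e-10. $\varepsilon$ is
configurable for sensitivity analyses but there is rarely a reason to
move it. Whether the transform runs before or after feature selection
does not change any result (Pearson correlation is computed on the same
values either way); the package fixes transform-first for determinism of
the code path.

## Feature selection

For a numeric or binary target, `cpg_correlations()` computes each
probe's Pearson correlation with the target (a 0/1 coding gives the
point-biserial case with the identical formula), and `select_top_k()`
keeps the k probes of largest **absolute** correlation. Ranking by |r| is
a deliberate choice where signed ranking would also have been defensible:
hyper- and hypomethylation both carry signal, and every downstream model
is sign-agnostic. Probes with zero variance get r = 0 rather than NA so
the ranking stays total, and ties break lexicographically by probe ID so
the selection is reproducible across platforms. For a multi-class target
(race/ethnicity), `select_union_per_class()` correlates probes against
each one-hot class indicator and returns the union of per-class top-k
lists; a catch-all "Other" class is excluded from selection because its
indicator is not a coherent biological contrast. The union size is
bounded between k and k × #classes, which the tests assert.

No multiple-testing filter is applied at selection time: selection ranks,
it does not test. A consequence worth knowing: when features are selected
on the full data set, later cross-validation folds are not fully
independent of the selection, so out-of-fold metrics are mildly
optimistic at small n. This matters for interpreting the synthetic
results (below) and for any small-cohort application.

## Classifiers

Smoking and race/ethnicity are random forests (`ranger` backend, impurity
importances, single-threaded for determinism). `grid_search_rf()` sweeps
every combination of forest size (20, 50, 100, 200, 500, 1000, 2000
trees) and maximum depth (2–7) — 42 configurations — scoring each by mean
accuracy over a 5-fold cross-validation whose fold assignment is fixed
across cells, so cells are compared on identical splits. Ties break
toward fewer trees, then shallower trees (parsimony). Folds are
stratified by class: with class counts as imbalanced as a real cohort's
(the smallest ancestry group is ~1.4% of samples), unstratified folds can
starve a class entirely; stratification is switchable off via
`stratify = FALSE`. Remaining forest hyperparameters
(features per split, bootstrap) follow `ranger` defaults and are recorded
in the fit's provenance.

`confusion_stats()` reports the truth × prediction table, overall
accuracy, Cohen's kappa with chance agreement from the row/column
marginals, and one-vs-rest sensitivity/specificity/balanced accuracy per
class. For smoking, the declared positive class is "Smoker", so
sensitivity is smoker recall. The implementation is written out rather
than delegated so that the test suite can verify it two independent ways
(a brute-force recount over label pairs, and `caret::confusionMatrix`).

## Regressors

Alcohol (as a 0–1 score: 1 = no alcohol … 0 = 15+ drinks/week, the three
intermediate categories evenly spaced at 0.75/0.5/0.25 — the endpoints
are fixed by the scoring convention, the even spacing is this package's
choice and overridable), BMI, and chronological age are feed-forward
networks trained full-batch with Adam under MSE loss and 5-fold CV, with
the final model refit on all data. Architecture presets mirror the swept
designs: no hidden layer, (2000), (2000, 500), (2000, 500, 50), all with
ReLU between layers and a linear scalar readout.

The reference training protocol is Adam at learning rate 1e-6 for 2,500
epochs. Three numerical choices make training behave well and are the
package's own:

* **Per-feature standardization** on the training fold (applied to
  held-out data with the training fold's statistics). Raw M values span
  tens of units with heterogeneous variances; standardization puts every
  input on a comparable scale. It is switchable (`standardize = FALSE`).
* **Target centering**: networks are trained against $y - \bar y$ and the
  mean is added back at prediction. Adam's per-coordinate steps are
  bounded by the learning rate, so without centering the output bias
  would need thousands of epochs just to traverse the target mean
  (~55 years for age).
* **A dead-rectifier guard**: occasionally an initialization strands a
  small network in a regime where entire hidden layers output zero and
  the training loss plateaus near var(y). If the final training MSE
  exceeds half the target variance, training restarts from up to two
  fresh (deterministically derived) seeds and the lowest-loss run is
  kept. This never triggers on healthy fits and is deterministic given
  the config seed.

Weight initialization is a seeded uniform fan-in scheme
($U(\pm 1/\sqrt{d_{in}})$), biases start at zero, and there is no
mini-batching — gradients are full-batch, matching the protocol's
asymptotic, slow-approach character. On the small synthetic problems used
in tests, a faster non-reference protocol (lr 0.01–0.05, 120–400 epochs)
reaches the loss plateau in seconds; each fit records its protocol in
`provenance`, with `reference_protocol = TRUE` only for the lr 1e-6 /
2,500-epoch settings.

`regression_metrics()` reports OOF Pearson r (two-sided p from the t
transform), MAE, and RMSE; `delta_age()` is predicted minus chronological
age, so positive values mean accelerated epigenetic aging.

## The explainable clock

`build_masks()` turns an annotation bundle into two binary connectivity
matrices: CpG × gene (1 iff the probe is annotated to the gene; probes
annotated to several genes fan out to all of them) and gene × gene-set
(1 iff the gene is in the set). Unannotated CpGs are dropped; genes in no
set, and sets with no retained gene, are pruned — they could not
influence the output and would only inflate the width of the dense
control. `train_masked_ffnn()` then fits CpG → gene → set → age with ReLU
after the gene and set layers (the generic recipe; rectifying the set
layer too keeps the two hidden layers symmetric) and a linear readout.
Masking is enforced multiplicatively on weights **and** gradients after
every optimizer step, so masked-zero weights are exactly zero at every
checkpoint — an invariant the tests probe mid-training, not just at the
end. `train_control_ffnn()` fits the fully connected control with
identical layer widths.

Explainability readouts: `pathway_activations()` returns the post-ReLU
set-layer values per sample (the per-sample "pathway weights" of a
prediction), and `top_weighted_sets()` ranks sets by the absolute weight
of their output connection, ties broken by name.

### A caveat on weight-based set importance

The output-weight ranking is scale-confounded: a set whose neuron
aggregates many coherent inputs has a large activation scale, needs only
a small output weight, and can rank *below* sets that contribute little.
Under Adam this is aggravated because every weight moves at a similar
step size, so in-sample-useful noise sets drift upward late in training.
The planted-pathway recovery scenario (below) is therefore designed with
matched scales — the planted set's CpG fan-in per gene and set size
resemble the other sets' — which is also the regime of a real array
annotation (~1.2 genes per annotated probe). On data where one set's
fan-in dwarfs the others, per-sample activations
(`pathway_activations()`) are the more faithful importance readout.

## Feature importance and enrichment

Forests report mean-decrease-in-impurity importances normalized to sum 1
(`rf_importance()`; an optional replicate-ensemble standard deviation
refits forests under shifted seeds, since the backend does not expose
per-tree importances). Networks are attributed by integrated gradients
(`deep_attribution()`): with baseline $b$ = the mean of the background
samples (by default the first 100 rows, matching the convention of
initializing an explainer on leading samples),
$a_i = (x_i - b_i) \int_0^1 \partial_i f(b + \alpha (x-b))\, d\alpha$,
evaluated by midpoint quadrature. Attributions satisfy completeness —
$\sum_i a_i = f(x) - f(b)$ — exactly for linear models and to
quadrature accuracy (O(1/steps), from rectifier kinks along the path)
otherwise; per-sample attributions are averaged, preserving sign, and
ranked by absolute value.

`top_n()` extracts the most important CpGs; `ora_genesets()` maps them to
genes (each gene counted once per hit list) and tests every set by the
upper-tail hypergeometric distribution against the universe of genes
annotated to any probe in the bundle, with BH adjustment across the
collection and the conventional FDR < 0.1 call. `genomic_feature_enrichment()`
applies the same tail test to CpG-island-relation and regulatory-group
categories against the whole-array background. `set_overlap_test()` and
`intersection_counts()` cover overlap p-values and UpSet-style exclusive
intersection counts. All hypergeometric tails are verified against
exhaustive counting for every urn with N ≤ 30.

## QC and association models

`pca_scores()` returns mean-centered PCA scores with a fixed sign
convention (largest-|loading| element positive). `batch_silhouette()`
reads the batch-effect screen as *one silhouette evaluation per
single component*: each principal component is treated as a 1-D embedding
and every batch's mean silhouette width is computed under
absolute-difference distance. This is the reading under which "batches
cluster across one of the components" is meaningful; positive widths flag
clustering, and singleton batches get width 0 by convention. Because a
handful of mildly positive widths arise by chance at modest n, the
calibration tests compare observed maxima against a permutation null
(re-computing widths under shuffled batch labels) rather than against
zero.

`fit_association()` is ordinary least squares of an outcome (delta age or
a predicted trait) on lifestyle, health, demographic, and technical
covariates, with categorical covariates contrasted against their largest
class (the stable choice under heavy imbalance), two-sided t-test
p-values, and BH adjustment across the model's non-intercept
coefficients. Rank-deficient designs error with the collinear columns
named. The estimated epithelial fraction enters these models as a
covariate but is never a training input for any predictor — cell
fractions are themselves derived from the methylation, so using them as
inputs would leak. `welch_t()` implements the unequal-variance t-test
with Welch–Satterthwaite degrees of freedom, with the degenerate
both-groups-constant case returning p = 1 (equal means) by convention.

`estimate_cell_fractions()` solves a nonnegative least-squares problem
per sample against reference cell-type profiles and rescales fractions to
sum ≤ 1. It deliberately implements the contract of reference-based
deconvolution — recover mixing weights from profiles — rather than any
specific published estimator, and is pluggable behind this one interface.

## What the synthetic generator emulates

`generate_cohort()` produces metadata shaped like a large adult US buccal
cohort: ages uniform on 18–93, ~23% smokers, six race/ethnicity classes
at realistic imbalance (the largest ~67%, the smallest ~1.4%), a
five-level weekly-alcohol category binned from a zero-inflated lognormal
latent consumption (which is what makes the 0–1 regression target
meaningful), continuous BMI, 0–1 lifestyle scores, cell-fraction columns,
and round-robin plate labels. Signal is planted on the M scale — where
the models train, keeping effect sizes interpretable — at fixed leading
probe blocks: linear in age (default 0.02 M/year, ≈1.5% methylation per
decade at mid-range, with random sign), a mean shift for smokers (1.0 M),
linear in BMI and the alcohol score, per-class ancestry shifts, optional
plate offsets on a probe subset, and Gaussian M-noise (default sd 0.5).
Betas are produced by the inverse-M logistic, so they always lie in
(0, 1). Everything is seed-deterministic.

The generator does **not** emulate: probe chemistry or detection
p-values, the beta-mixture shape of real arrays beyond what the logistic
transform induces, correlated CpG blocks (probes are independent given
covariates), nonlinear dose–response except for the optional hinge-shaped
age component, or realistic annotation topology beyond random
probe→gene→set membership. Passing recovery tests on these cohorts shows
the *machinery* is correct — selection finds planted probes, models
recover planted effects, masked training respects annotations, QC flags
planted shifts — not that any particular accuracy will transfer to real
buccal data, where effect sizes, probe correlation, and annotation
structure all differ.

Where the generator needed values the cohort description does not pin
down (per-variable effect sizes, noise level), they were chosen once to
be realistic for buccal arrays and to make planted signal recoverable at
desk scale, and are not revisited per test.

## Test and demonstration problem sizes

The recovery scenarios run at n = 500 samples × 5,000 probes with 300
planted age CpGs (age clock, smoking forest, architecture comparison),
and the networks use two hidden layers of widths (64, 16) — the reference
depth at desk-scale width. The planted-pathway scenario uses 30 planted
age CpGs funneled through 20 reserved genes into one gene set, with
selection k = 90, so the funnel is identifiable and scale-matched (see
the caveat above); there, the masked model recovers the planted set at
the top of the weight ranking while remaining at or below its dense
control's OOF correlation, the ordering expected when sparsity constrains
a model that the dense control can match. The batch-screening scenario
plants a 1.5 M-unit plate offset on 10% of probes across two plates.
The full test suite and the acceptance script each run in about a minute
on one CPU.

## Known limitations

* OOF metrics inherit the optimism of full-data feature selection
  (discussed above); a nested selection scheme is out of scope.
* The desk-scale training protocol is not the reference protocol; at
  reference settings (lr 1e-6, 2,500 epochs, widths 2000/500/50) training
  a 10,000-input network is a multi-hour job.
* Weight-based set importance is scale-confounded (see caveat); prefer
  activation readouts when fan-ins are heterogeneous.
* The hinge is the only nonlinearity the generator can plant; tests of
  "hidden layers help" speak to that nonlinearity class only.
* No higher-order pathway roll-ups: sets are flat collections.
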