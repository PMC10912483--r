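---
title: "Multi-view graph convolutional classification of multi-omics cohorts: methods and design"
author: "mvGCN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view graph convolutional classification of multi-omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvGCN)
```

## The problem

Cancer grading and subtyping tasks come with several molecular measurement
layers per patient — typically mRNA expression, DNA methylation and copy
number variation — each high-dimensional ("large p, small n") and each
carrying partly complementary class signal. mvGCN classifies patients by
treating each omics layer as a *view*: the cohort becomes a graph whose
nodes are patients, each view contributes its own patient similarity
network and its own graph convolutional encoder, and a learned attention
mechanism decides, per patient, how much each view's embedding contributes
to the final softmax classification. Training is semi-supervised and
transductive: all patients are present in the graphs; only the labels of
the training fold enter the loss.

## The pipeline stage by stage

### Feature selection

Each view is reduced independently by a three-step cascade
(`selectFeatures()`):

1. **Chi-square screening.** Omics values are continuous, so the
   contingency table underlying the statistic is built from non-negative
   *feature mass*: the observed value for class $c$ is the sum of the
   feature over the samples of class $c$, the expected value is the class
   share of the feature total, and the score is
   $\sum_c (O_c - E_c)^2 / E_c$. This requires non-negative values; views
   with negatives (CNV log ratios) are min-max shifted per feature first.
   The top `kChi2` features (default 5000) survive.
2. **Linear min-max normalization** of every surviving feature to
   $[0,1]$; constant features map to 0.
3. **Greedy mRMR** (`mrmrSelect()`) under the difference (MID) criterion
   $I(f; y) - \frac{1}{|S|}\sum_{g \in S} I(f; g)$, where $I$ is discrete
   mutual information after per-feature quantile discretization into
   `bins` equal-frequency bins (default 5, a standard choice balancing
   resolution against the sample sizes of a few hundred patients typical
   here). The top `mMrmr` features (default 500) are kept.

Ties everywhere break by ascending feature index, making the cascade
fully deterministic. Quantile binning and the MID form were design
choices: the mutual-information estimator for continuous omics data is
not canonical, and equal-frequency bins are robust to the skewed
marginals of expression data. Selection is fit once on the full cohort
before cross-validation, matching the preprocessing-before-CV protocol
this design follows; note this lets test samples influence which features
are kept (selection bias), so fold-level metrics characterise the
transductive protocol rather than prospective generalisation.

### Patient similarity networks

Per view, cosine similarity $S_{ij}$ between patient profiles is
thresholded into a weighted adjacency: $A_{ij} = S_{ij}$ when $i \ne j$
and $S_{ij} \ge \epsilon$, else 0. The threshold is not set directly but
derived from a target average degree $k$: $\epsilon$ is the
$\lceil nk \rceil$-th largest off-diagonal similarity (ordered pairs,
diagonal excluded), the smallest edge set whose average degree reaches
$k$. The default $k = 5$ keeps the graph sparse enough that propagation
stays local while every patient typically retains neighbours; the
realized degree is available via `realizedDegree()` and exceeds $k$ only
by tie multiplicity. A threshold $\le 0$ is rejected rather than silently
admitting negative edge weights, because the propagation operator
requires a non-negative adjacency.

The GCN propagation operator is the renormalized adjacency
$\tilde A = \hat D^{-1/2}(A + I)\hat D^{-1/2}$, whose spectral radius is
at most 1 (the suite asserts this on random graphs); an isolated patient
reduces to an identity row, i.e. pure self-information.

### Encoders, attention fusion, classifier

Each view gets a three-layer GCN: $H^{(l+1)} = \sigma(\tilde A H^{(l)}
W^{(l)})$ with $\sigma$ = ReLU after layers 1 and 2 and no activation
after layer 3, plus two inverted-dropout layers (rate 0.5) after layers 1
and 2, active only during training. Three layers is a deliberate depth:
deeper stacks over-smooth node embeddings toward uniformity (a regression
test demonstrates this on a cycle graph with propagation-only layers),
while fewer layers underuse the neighbourhood structure.

Per-view embeddings $h_{iv}$ are fused by a shared attention scorer:
$e_{iv} = a^\top \tanh(W_a h_{iv})$, $\alpha_{i\cdot} =
\operatorname{softmax}_v(e_{i\cdot})$, fused embedding
$\sum_v \alpha_{iv} h_{iv}$. Design choices worth noting: the scorer
($a$, $W_a$) is shared across views so that identical embeddings provably
receive uniform weights; attention is computed *per node*, so different
patients may weight the omics layers differently; and a bounded $\tanh$
projection is used for the score nonlinearity, which keeps scores in a
fixed range regardless of embedding scale. The $\alpha$ matrix is
returned by every forward pass, making the fusion auditable. With a
single view the stage reduces exactly to the identity.

A linear map plus softmax produces class probabilities; hidden widths
default to (400, 400, 200) with a 64-dimensional attention projection,
conventional sizes for cohorts of several hundred patients and 500
features per view.

### Training

The loss is masked cross-entropy over the training indices,
$-\sum_{l \in Y_L} \ln p_{l, y_l}$, divided by the mask size by default
so the learning-rate scale is independent of how many nodes are labelled
(`reduce = "sum"` recovers the plain sum). Optimization is full-batch
Adam (default learning rate $10^{-3}$, weight decay $5 \times 10^{-4}$),
with gradients derived analytically through the classifier, the
attention softmax, and the three convolutions; a finite-difference test
verifies them to $10^{-4}$ relative error. Early stopping monitors the
validation loss: training halts once no improvement of at least
`minDelta` ($10^{-4}$) has occurred for `patience` (default 100)
consecutive epochs, and the parameters from the best validation epoch
are restored. "Improvement" is measured against the best loss seen so
far, so `patience = 1` with an infinite `minDelta` stops at epoch 2 with
epoch 1 as the best — the degenerate case pinned by a test.

### Cross-validation harness

`makeFolds()` produces stratified K folds (default 5) and holds out a
stratified fifth of each training portion for early stopping. Every class
must have at least `nFolds` members — a cohort with an 11-patient class
still admits 5 folds, and smaller classes fail loudly by name.
`crossValidate()` builds the graphs once from all samples (transductive),
trains per fold, and aggregates mean ± sd per metric;
`viewAblation()` repeats this for all $2^V - 1$ view subsets.
Determinism is end to end: every stochastic step (cohort generation,
folds, weight initialisation, dropout) derives from explicit integer
seeds, and identical configuration plus seed reproduces the CV summary
bitwise.

### Metrics

Binary tasks report accuracy, F1 and the Mann-Whitney (pairwise) AUC,
computed via midranks so ties contribute one half; the suite cross-checks
it against an independent trapezoidal ROC integration on tie-free
instances. Multiclass tasks report accuracy, support-weighted F1 and
macro F1. Macro F1 here is the **harmonic mean of macro-averaged
precision and macro-averaged recall**, not the mean of per-class F1
scores — the two definitions genuinely differ on imbalanced confusion
matrices, and a test documents the divergence. Degenerate denominators
(e.g. precision with no predicted positives) yield 0 with a warning.
Weighted F1 weights per-class F1 by true-class support.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the pipeline
assumes: $V$ aligned views over the same samples, labels drawn from a
class-proportion simplex, a sparse informative feature subset per view
carrying class-dependent Gaussian mean shifts (adjacent class means
separated by `effectSize` feature standard deviations), everything else
pure noise, and a per-view global shift to non-negative values — a shift,
not a truncation, so the covariance structure is preserved. A
heavy-tailed option (t with 3 df) exists for robustness checks.

`simulateComplementaryCohort()` is the fusion stress test: three classes,
three views, view $v$ shifting only one class pair ($\pm$ half the effect
size), so each view cleanly separates one pair while the remaining class
sits midway. Defaults are 5 informative features of 100 and effect size
1.5, chosen from the Gaussian error analysis: with those values a single
view's Bayes-optimal accuracy is around 0.8 (the midway class overlaps
both pair members at $\approx 1.7\sigma$ Mahalanobis separation), while
the union of views separates every pair at $\approx 3.4\sigma$ — so
fusion has genuine headroom, which is exactly what the
fusion-beats-single-view comparison needs. These cohorts deliberately do
not reproduce real CNV segment structure, methylation beta-value
distributions, or batch effects; passing tests demonstrate that the
machinery recovers planted signal under the stated noise model, not that
any particular performance level transfers to real cohorts.

## Problem sizes and numerical choices in the shipped experiments

The packaged tests and the acceptance script run the pipeline at
desk scale, chosen so a full run completes in minutes on one CPU while
every stage still operates well above degeneracy: cohorts of 150–300
samples, 100–500 features per view reduced to 20–30, hidden widths
(16, 16, 8) with a 4-dimensional attention projection, learning rate
$10^{-2}$ (full-batch Adam on these small widths converges in roughly
100–250 epochs; the $10^{-3}$ default is conservative for the
full-size architecture), and 5-fold CV. The fusion experiment uses 10
generator seeds and a paired sign test.

Numerical conventions collected in one place: constant features min-max
normalize to 0; all-zero patient profiles get similarity 0 off-diagonal
and 1 on the diagonal; ties at the similarity threshold are all kept
(inclusive $\ge$); tie-breaks in rankings are by ascending feature index;
probabilities are clamped at the smallest positive double before logs;
softmax subtracts the row maximum for stability.

## Known limitations

- Full-cohort feature selection and transductive graphs mean test
  samples shape both the feature set and the propagation operator;
  fold metrics measure within-cohort label recovery, not deployment
  performance on unseen patients.
- The chi-square stage's feature-mass contingency construction is one of
  several defensible adaptations of the test to continuous data.
- The mutual-information estimator (quantile binning) is biased for
  small samples; with very few samples per class consider fewer bins.
- No minibatching: the dense $n \times n$ propagation limits cohorts to
  a few thousand patients.
- Class imbalance is not reweighted by default; severely imbalanced
  tasks may want the `reduce = "sum"` loss with external weighting or
  resampling upstream.
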