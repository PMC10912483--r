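# mvGCN

Semi-supervised classification of cancer patients from multiple omics
layers (for example mRNA expression, DNA methylation and copy number
variation measured on the same cohort), for researchers studying tumor
grading and molecular subtyping. The package implements the whole
multi-view graph neural pipeline in R — feature selection, patient
similarity networks, per-view graph convolutional encoders, attention
fusion, and a cross-validation harness — together with a synthetic
multi-omics cohort generator so every stage is testable without any
external download.

## The model

Each omics view $v$ is a matrix $X_v \in \mathbb{R}^{n \times d_v}$ over
the same $n$ patients. Per view:

1. **Feature selection**: chi-square screening (top $k$, default 5000)→
   min-max normalization to $[0,1]$ → greedy mRMR under the difference
   criterion $I(f;y) - \frac{1}{|S|}\sum_{g \in S} I(f;g)$ (top $m$,
   default 500).
2. **Patient similarity network**: cosine similarity
   $S_{ij} = x_i \cdot x_j / (\lVert x_i\rVert\,\lVert x_j\rVert)$,
   thresholded at the smallest $\epsilon$ whose edge set
   $\{S_{ij} \ge \epsilon\}$ preserves an average degree $k$ per node
   (weighted edges, default $k = 5$), then renormalized as
   $\tilde A = \hat D^{-1/2}(A + I)\hat D^{-1/2}$.
3. **Encoder**: three stacked graph convolutions
   $H^{(l+1)} = \sigma(\tilde A H^{(l)} W^{(l)})$ with ReLU activations
   and two dropout layers.

Per-view node embeddings $h_{iv}$ are fused with a shared attention
scorer, $e_{iv} = a^\top \tanh(W_a h_{iv})$ and
$\alpha_{i\cdot} = \operatorname{softmax}_v(e_{i\cdot})$, then classified
by softmax. Training minimizes the masked cross-entropy
$-\sum_{l \in Y_L} \ln p_{l, y_l}$ over the labelled training nodes with
full-batch Adam and validation-loss early stopping; the protocol is
transductive (all patients sit in the graphs, only labels are masked).
Evaluation uses stratified 5-fold cross-validation with accuracy,
Mann-Whitney AUC and F1 for binary tasks, and accuracy, support-weighted
F1 and macro F1 (harmonic mean of macro precision and macro recall) for
multiclass tasks. See `vignettes/mvGCN-methods.Rmd` for the full account.

## Worked example

```r
library(mvGCN)

# a synthetic 3-class cohort: two views, 12 informative features each
sim <- simulateCohort(120, c(0.5, 0.3, 0.2), views = list(
  list(name = "mRNA", nFeatures = 150, nInformative = 12, effectSize = 1),
  list(name = "meth", nFeatures = 120, nInformative = 12, effectSize = 1)),
  seed = 42)
al  <- alignViews(sim$views, sim$labels)
sel <- lapply(al$views, function(v)
  selectFeatures(v, al$labels, kChi2 = 100, mMrmr = 25)$view)
sel[[1]]
#> OmicsView 'mRNA': 120 samples x 25 features
#>   range [0, 1]

buildPatientGraph(sel[[1]], k = 5)
#> PatientGraph: 120 patients, epsilon = 0.9312
#>   target average degree 5.00, realized 5.00

cfg <- defaultConfig()
cfg$model$hiddenDims <- c(16L, 16L, 8L); cfg$model$attentionDim <- 4L
cfg$training$lr <- 1e-2; cfg$training$maxEpochs <- 150L
cfg$training$patience <- 40L; cfg$training$seed <- 42L
crossValidate(sel, al$labels, cfg)
#> Cross-validation over 5 folds
#>   accuracy    0.9833 +/- 0.0229
#>   f1Weighted  0.9831 +/- 0.0231
#>   f1Macro     0.9858 +/- 0.0194
```

The feature cascade kept 25 normalized features per view; the patient
graph hit its target average degree exactly (threshold 0.93); and 5-fold
cross-validation recovers the three planted classes at 98% accuracy.
`crossValidate` returns the per-fold table, the fold splits, the
training histories and the graphs; `viewAblation()` repeats the run for
every view subset to quantify what each omics layer contributes.

A thin command-line wrapper with `simulate` / `preprocess` /
`build-graph` / `cv` / `score` subcommands ships in
`inst/cli/mvgcn.R`.

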