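# gnnsurv

Graph neural network survival models for whole-slide histopathology
images, in R.

Rare-cancer cohorts — the motivating case is primary mucinous ovarian
carcinoma, an epithelial ovarian cancer subtype with no reliable
prognostic markers — are too small for conventional deep learning yet
too heterogeneous for single hand-crafted features. This package
implements a graph-based survival pipeline for such settings: each
whole-slide image (WSI) becomes a spatial graph of tissue patches, a
graph neural network pools the patch features into one slide
embedding, and a Cox proportional hazards head turns the embedding
into a risk score, trained end-to-end on censored survival data. It is
aimed at computational pathology researchers who want a transparent,
fully testable reference implementation that runs on synthetic data
end-to-end, with clean interfaces for plugging in real slides and a
pretrained patch encoder.

## The model

For slide *s* with patch features `x_1..x_N` (512-dim) and k-NN edges
(k = 8, Euclidean distance between patch centres at x5):

1. Message passing (GCN `D^{-1/2}(A+I)D^{-1/2} H W` or 4-head GAT),
   512 → 256 → 128, then a node-level linear map to 64 dims.
2. Graph pooling (KDE / attention / max / mean) to one 64-vector `g_s`.
3. Risk score `r_s = β' g_s`; no intercept (absorbed by the baseline
   hazard).

Training minimises the negative Cox partial log-likelihood with the
Breslow convention for ties,

```
L = − Σ_{i : event} [ r_i − log Σ_{j : t_j ≥ t_i} exp(r_j) ],
```

jointly over the network weights and β (full-batch Adam; hand-derived,
finite-difference-verified gradients). Patient risk is the maximum over
the patient's slides; the Breslow estimator of the cumulative baseline
hazard converts scores to 18-month survival probabilities
`S(t|r) = S0(t)^exp(r)`, thresholded into high/low risk groups.
Evaluation is 4-fold patient-level cross-validation with Harrell's
C-index. An edge-mask explainer scores each patch's contribution to
the risk and renders blue-to-red heatmaps. The accompanying statistics
module (chi-square/Fisher, Mann-Whitney, Kaplan-Meier, log-rank,
uni-/multivariable and lasso Cox) covers the cohort-validation
analyses around the model.

Everything is exercisable without external data: `simulate_slide()`
generates stained-slide images with ground-truth masks for the
segmentation stage, and `simulate_cohort()` generates patient cohorts
of patch graphs whose survival times follow a proportional-hazards law
driven by a planted graph-level signal.

## Worked example

```r
library(gnnsurv)

# a synthetic 24-patient cohort with planted prognostic signal
cohort <- simulate_cohort(cohort_sim_config(
  n_patients = 24, slides_per_patient = c(1, 2),
  nodes_per_graph = c(12, 24), feature_dim = 64,
  signal_dim_count = 8, beta_true = 2, seed = 11))

fit <- gnnsurv(cohort$graphs, cohort$survival,
               backbone_config("gcn", hidden_dims = c(32, 16),
                               embed_dim = 16, kde_grid = 8),
               train_config(epochs = 60, seed = 11))
fit
#> Joint GNN-Cox survival model (GCN + kde pooling)
#>   37 slides, 24 patients (15 events)
#>   final loss 38.5707 (from 65.4175), training C-index 0.831

# held-out performance and risk stratification
cv <- cross_validate(cohort$graphs, cohort$survival,
                     backbone_config("gcn", hidden_dims = c(32, 16),
                                     embed_dim = 16, kde_grid = 8),
                     train_config(epochs = 60, seed = 11),
                     n_folds = 4, seed = 11)
cv
#> 4-fold patient-level CV (GCN + kde)
#>   per-fold C-index: 0.5833, 0.6667, 0.6250, 0.7692
#>   mean C-index: 0.6611
#>   stratification at S(18 mo) < 0.9: 6 high / 18 low
```

The training C-index (0.831) exceeds the cohort's information ceiling —
with `beta_true = 2` the concordance of the *true* risk is about 0.65
(see the methods vignette) — which is the signature of overfitting a
small cohort; the cross-validated mean (0.66 here) is the honest
number and sits at that ceiling. The 18-month stratification and
downstream group comparisons (`logrank_test()`, `cox_table()`,
`group_comparison_table()`) then quantify whether the two risk groups
separate in survival.

For real slides, the same pipeline starts from images:

```r
slide <- open_slide("slide.tiff", base_magnification = 40)
graph <- slide_to_graph(slide, k = 8)          # mask -> tile -> encode -> k-NN
em    <- explain_graph(fit, graph)             # per-patch importance
heat  <- render_heatmap(em, slide)             # blue -> red overlay
```

A thin command-line front end over these functions lives at
`inst/cli/gnnsurv.R` (subcommands `run`, `simulate`, `mask`,
`build-graph`, `evaluate`, `explain`), and `run_pipeline()` executes
the whole chain from one YAML config with a manifest (seed, config
hash, per-stage wall times).

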