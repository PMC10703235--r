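---
title: "Hierarchical cluster-based local regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cluster-based local regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Linear calibration models such as partial least squares regression (PLSR)
perform poorly when a data set contains several groups with different
X–Y relationships: a single model is dominated by the between-group
structure and predicts something close to each group's average.  When the
data are at least locally well behaved, splitting the samples into more
homogeneous clusters and calibrating one model per cluster recovers the
lost accuracy and — just as importantly — lets each local model be
interpreted on its own terms.

`hclocal` implements this hierarchical cluster-based (HC) procedure:

1. **Global PLSR.**  A NIPALS PLSR model is calibrated on the full
   training set; the component count minimizes the cross-validated MSE
   (10-fold by default, leave-one-out for small data).
2. **Clustering in score space.**  The global model's X-scores are
   clustered with fuzzy c-means (FCM, Euclidean distance, fuzzifier
   `m = 2`).  Ward-linkage agglomerative clustering (HAC) and
   normalized-cuts spectral clustering (SPC) are available as crisp
   alternatives.
3. **Small-cluster reassignment.**  Members of clusters with fewer than
   10 samples are moved to their highest-membership cluster among those
   meeting the minimum, until every surviving cluster has at least 10
   members.
4. **Local calibration.**  One regressor per cluster — PLSR,
   epsilon-SVR with a kernel × cost grid search, a small 1D convolutional
   network (5 filters, kernel 11, ELU, max-pool, linear head) or a
   two-layer recurrent network (32 and 16 units, ELU, linear head) —
   each with its own cross-validated hyperparameters.
5. **Classifier routing.**  Classifiers (FCM membership, LDA, QDA,
   Gaussian naive Bayes) are calibrated on the scores versus the crisp
   cluster labels.  A new sample is projected into the global score
   space, classified, and predicted by its cluster's local model
   ("closest" mode; an FCM-membership-weighted sum of all local
   predictions is available but not the default, since routing to the
   closest model generally predicts better).

The number of clusters can be selected with `select_n_clusters()`: the
training set is split 50/50 into calibration and validation halves,
hierarchical models for k = 2…10 are fitted on the calibration half, and
the winner is the smallest k whose mean validation R² over the four
classifier methods lies within one standard error of the maximum (the
usual one-standard-error parsimony rule, with the asymptotic standard
error of R² on the validation half); exact ties also go to the smaller
k.  The final model is then refitted on the full training set.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| PLS components | CV-min MSE | Standard chemometric choice; an optional restraint drops components adding < 1% incremental explained X-variance, useful for ill-conditioned spectra where the raw CV minimum is absurdly high. |
| FCM fuzzifier `m` | 2 | The canonical Bezdek default; `m → 1` approaches k-means. |
| FCM restarts | 10 | FCM has local minima; the lowest-objective fit is kept. |
| Minimum cluster size | 10 | Local models below this cannot be validated meaningfully. |
| SVR grid | {linear, radial, sigmoid} × C = 10^(−4…6) | Kernel set and cost range for the local-model search; epsilon 0.1 on the standardized response. |
| Network epochs | ≤ 1000, checkpoint every 50 | The epoch count is picked from validation checkpoints (holdout by default, k-fold optional) and the network is refitted on all data at that count. |
| Optimizer | Adam, lr 0.001, batch 32 | Standard defaults; the activation × learning-rate grid (`activation_lr_grid()`) covers sigmoid/ReLU/ELU/tanh/linear × 0.1…0.0001. |

Scaling conventions: X is mean-centred for PLSR and mean-centred and
standardized for SVR/CNN/RNN; responses are standardized internally by
the non-linear learners and predictions returned on the original scale.

## The score-space metric

A deliberate design choice, and the one place this implementation departs
from the straightforward recipe: clustering and classification operate on
score columns divided by the norm of their projection directions
(`score_scaling = "unit-direction"`).  Raw NIPALS scores are `X R` with
`R = W (PᵀW)⁻¹`; the columns of `R` are not unit vectors, and on data with
isotropic within-cluster noise the later score axes can amplify that
noise several-fold while carrying little between-cluster separation.  In
experiments on the simulated benchmark this amplification intermittently
collapsed two well-separated clusters into one FCM cluster.  Dividing
each score column by `‖r_a‖` makes every axis carry within-cluster noise
at its feature-space scale (unit variance for isotropic noise), which
restores the premise that well-separated groups in X stay separated in
score space.  `score_scaling = "none"` gives the raw-score variant.

## What the simulated benchmark emulates

`simulate_hc_dataset()` rebuilds the three-cluster benchmark: 1500
samples with 20 features drawn from three isotropic Gaussian blobs
(sd 1, centres uniform in [−10, 10]^20), with responses from the three
classical Friedman test functions — one function per cluster.

Two aspects of this construction are under-determined and fixed here by
design:

* **Centre separation.**  Centres are redrawn until every pair is at
  least 20 apart in the full feature space *and* proportionally apart
  (20·√(5/20)) within the first five coordinates, the ones that carry
  the response.  Without the second criterion, occasional draws place
  two centres nearly on top of each other in the response-relevant
  coordinates, so those two clusters no longer realize *different*
  X–Y relationships — contradicting what the benchmark is meant to test.
* **Coupling of features to responses.**  The Friedman functions
  canonically draw their own uniform inputs.  Here the first `d` features
  of each cluster (d = 5 for variant 1, d = 4 for variants 2–3) are
  min–max mapped onto the variant's canonical input box and fed to the
  formula; the remaining features are distractors that carry cluster
  location but no response signal.  Because a Gaussian sample min–max
  mapped onto a box concentrates in the box centre, the effective input
  distribution is centre-heavy rather than uniform; this makes the
  arctangent variant (#3) operate mostly in its saturated regime, where
  even flexible learners top out well below the other two variants'
  accuracy.  This is the main reason absolute benchmark accuracies
  reported by `scripts/acceptance.R` sit below some published analyses
  of similar designs, while the qualitative contrast — hierarchical PLSR
  far above global PLSR — is robust.
* **Response scales.**  Each cluster's responses are standardized to
  mean 0, sd 1 (`per_cluster_standardize = TRUE`).  Raw Friedman scales
  differ by orders of magnitude between variants; without
  standardization the benchmark degenerates into predicting cluster
  means.  Response noise defaults to 0 so the benchmark probes model
  structure, not noise robustness.

What passing these benchmarks does *not* show: the generator's clusters
are isotropic, equally sized and noise-free, so success here says nothing
about unequal cluster sizes, heteroscedastic noise, or drifting
instrument baselines in real spectra.  The FT-IR-like generator
(`make_synthetic_spectra()`) covers multiplicative scatter, polynomial
baselines and replicate structure, but real dry-film spectra also carry
water-vapour lines, detector nonlinearity and wavenumber calibration
error, none of which are modelled.

## Spectral preprocessing

The chain for FT-IR dry-film data is fixed in the order: replicate
averaging → Savitzky–Golay second derivative (window 11 points, third
order polynomial) → EMSC with second-order polynomial correction against
the mean spectrum → cropping to 1800–700 cm⁻¹ (inclusive bounds) →
centring (PLSR) or centring + standardization (SVR/CNN/RNN).
Savitzky–Golay filtering uses one-sided polynomial fits at the spectrum
edges so the feature count is preserved for the subsequent crop; EMSC is
fitted before cropping; the EMSC polynomial uses plain powers of the
axis rescaled to [−1, 1] for conditioning.  A fitted chain stores the
EMSC reference and centring statistics and re-applies them unchanged to
new data.

## Numerical choices

* NIPALS converges on a weight-vector change below 1e-10, at most 500
  inner iterations; extraction stops early when a score's sum of squares
  falls to numerical zero (rank exhaustion).
* Component selection takes the *smallest* count within float tolerance
  of the CV minimum, so exact ties (noise-free data) resolve to the
  parsimonious model.
* A sample coinciding with an FCM centroid receives membership 1 for
  that centroid (the limit convention).
* Covariances that are singular for LDA/QDA are ridge-regularized by
  `1e-8 · trace/dim` on the diagonal, with a warning; naive Bayes floors
  per-feature variances similarly.
* The SVR grid search runs on at most `grid_subsample` (400) training
  samples and stops walking each kernel's ascending cost path once the
  CV curve has descended and then saturates (< 1% improvement) or
  worsens; the winning cell is refitted on all data.  This avoids the
  pathologically slow large-cost linear-kernel optimizations whose
  solution no longer changes.
* Divergent network training (non-finite or absurdly large loss on the
  standardized scale) aborts with a diagnostic; grid-search cells record
  the failure instead of propagating it.
* Cross-fold cluster correspondence is resolved by the best
  label-overlap permutation (exhaustive for k ≤ 7, greedy above).

## Problem sizes used by the shipped benchmarks

The test suite and `scripts/acceptance.R` run the full 1500-sample
benchmark, with 10 replicates for the PLSR and SVR comparisons and 3–5
replicates at reduced epoch budgets (CNN 200–1000, RNN 80–300 epochs,
holdout epoch selection, SVR grid search on a 250-sample subsample with
5-fold CV) for the network comparisons.  These are the package's chosen
desk-scale study conditions; larger budgets change the network results
only gradually.

## Known limitations

* The hierarchy is two-level by design; no nested clustering.
* Weighted prediction requires FCM clustering (crisp assigners provide
  no membership model for new samples; their distance-derived soft
  memberships serve only the reassignment rule).
* The FCM "classifier" cannot be trained on labels, so it is only valid
  when the clustering itself was FCM.
* Permutation importance shares credit across strongly collinear
  features (adjacent spectral channels); maps should be read as regions,
  not single channels.  VarGrad maps for the CNN are blurred by the
  convolution kernel's footprint.
* The networks are small by construction — the point of the framework is
  that local models can stay simple — and are not a general-purpose deep
  learning facility.
* On the simulated benchmark, cluster counts above the generating three
  can genuinely raise validation R² by splitting the saturated
  arctangent regime into locally simpler pieces, so the automated
  cluster-number selection does not always return the generating count
  even with the parsimony rule.
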