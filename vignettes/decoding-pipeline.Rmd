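---
title: "Cross-subject action-semantics decoding: methods and design notes"
author: "actdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject action-semantics decoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(actdecode)
```

## The decoding problem

The package decodes which of C = 39 action categories a subject was
watching, from per-stimulus GLM beta patterns, under the hardest
generalization regime: the decoder never sees the test subject. Rather
than classifying betas directly, it regresses them onto the deep
*action-feature* space of a video action-recognition network and converts
predicted features to category probabilities through the network's own
final linear layer. Separating regression from classification means the
label space can be extended by retraining only the readout, and the
regression target is a rich continuous space rather than a hard label.

Feature extraction itself (the 3-D convolutional network, its attention
mechanism and fine-tuning) is out of scope: features arrive as data, in an
`action_feature_space` holding the per-stimulus targets `y0`
(128-dim), auxiliary targets `y1` (432-dim pooled features one layer
earlier), and the readout `(W, b)`.

## Pipeline stages and their tunables

### Split-half voxel reliability

For voxel v, `voxel_split_half()` correlates the mean beta over
odd-indexed runs with the mean over even-indexed runs, across stimuli.
Within-set mode computes r inside each video set and averages the two
r-maps; cross-set mode correlates set-1 odd betas with set-2 even betas
(and the converse, averaged), pairing the sets' stimuli by category —
the only well-defined pairing when exemplars are not matched across sets.
With a single video set, cross-set mode falls back to the single set's
halves and flags the result (`single_set = TRUE`).

Numerical conventions:

* constant (zero-variance) series get r := 0 — a voxel that does not vary
  across stimuli carries no stimulus information, and Pearson r is
  undefined there;
* the selection boundary is inclusive (`r >= cutoff`), default
  `cutoff = 0.3`;
* `cutoff_curve()` reports per-video multi-voxel pattern reliability
  across candidate cutoffs; candidates leaving fewer than 2 voxels yield
  `NA` entries rather than errors. `suggest_cutoff()` implements a
  stabilization heuristic (first candidate whose median per-video gain
  falls below 0.005 per step) but is *never* applied silently — selection
  always uses the cutoff the caller passes.

Group-level selection (the default in practice) averages betas across
subjects run-by-run before correlating; single-subject maps are also
supported.

### PCA reduction

`fit_pca()` centers training rows and extracts up to k = 1,000
components. With 12 training subjects of 39 stimuli each there are only
468 training rows, so the rank cap `min(k, n − 1, n_voxels)` always
bites in the canonical setup; the cap is reported with a warning rather
than hidden, because silently fitting fewer components than requested is
a classic source of irreproducibility.

### Regression to the feature space

`fit_regressor()` fits one of four regressors behind a single interface:

| kind | description | key defaults |
|---|---|---|
| `multitask_mlp` | 3-layer MLP, auxiliary loss on the hidden layer | w0 = 2.2, w1 = 1 |
| `mlp` | same network, auxiliary weight forced to 0 | dropout 0.4 |
| `ridge` | closed-form L2 regression per output dimension | alpha = 0.2 |
| `knn` | k-nearest-neighbour regression, uniform weights | k = 7 |

The MLP maps k_eff PCA scores through a 432-unit hidden layer
(affine → batch normalization → ReLU → dropout 0.4) to the 128-dim
output. The hidden width equals the auxiliary feature dimension by
construction: the hidden layer's post-ReLU activation *is* the auxiliary
prediction, constrained toward `y1`. The loss sums squared error over
feature dimensions and averages over samples,

L = (1/n) ( w0 Σ_i ||y0_i − ŷ0_i||² + w1 Σ_i ||y1_i − ŷ1_i||² ),

optimized by plain SGD (learning rate 1e-4, batch 16, fixed epoch count,
seeded shuffling). Design points that were genuinely open, and how they
were resolved:

* **Where the auxiliary constraint attaches.** Dimensional match forces
  the 432-unit hidden layer; post-activation (pre-dropout) was chosen so
  the constrained quantity is exactly what feeds the final layer.
* **Loss reduction.** Sum over dimensions, mean over samples — this makes
  the printed 1/n prefactor exact and, at 128/432-dim targets, gives SGD
  at learning rate 1e-4 a usable effective step size.
* **Input scaling.** PCA scores are z-scored with training-fold
  statistics (targets are used raw); logged on every fit. Batch
  normalization uses batch statistics in training and running averages
  (momentum 0.1) at inference; dropout is disabled at inference, so
  prediction is deterministic. Remainder mini-batches of a single sample
  are skipped: batch statistics are undefined there.
* **SGD momentum** defaults to 0 (a config knob exists); no weight decay,
  no early stopping.
* **KNN "degree".** The baseline's distance is Minkowski with power 2
  (Euclidean) — the only standard reading of a polynomial-degree-style
  parameter equal to 2 for a KNN regressor.
* **Ridge parameterization.** Closed form `(X'X + αI)^{-1} X'Y` with an
  unpenalized intercept, i.e. α penalizes raw coefficients and is not
  scaled by n — matching the convention under which α = 0.2 is quoted.

### Mixup augmentation

`mixup_augment()` draws, per category, uniformly random same-category
pairs from *different* training subjects and forms
d = λ d_si + (1 − λ) d_sj with both target blocks interpolated by the
same λ. The mixing weight is fixed at λ = 0.2 by default; a
`Beta(α, α)` mode is available since the weight is described as
Beta-distributed with a finally selected value of 0.2 — the fixed value
is the only number actually given. The number of new samples per category
defaults to the training-subject count (roughly doubling the training
set). Augmentation operates on PCA-reduced samples, never raw voxels, and
only on training-fold subjects — `run_loso()` enforces the contamination
guard structurally by augmenting inside the fold.

### Readout and metrics

`softmax_readout()` computes Q = softmax(W ŷ0 + b) with a per-row
max-shift (logits of magnitude 1e4 stay finite; rows sum to 1 within
1e-9). `topk_accuracy()` ranks categories per stimulus; ties break
deterministically by ascending category index (documented), with a
randomized-tie mode used for chance-level simulation, where deterministic
tie-breaking on exactly uniform probabilities would be degenerate.
`pairwise_classification()` scores all unordered stimulus pairs by the
symmetric sum rule — correct when
corr(ŷ_i, y_i) + corr(ŷ_j, y_j) > corr(ŷ_i, y_j) + corr(ŷ_j, y_i) —
with a one-sided variant available; the symmetric rule is the common
convention in identification analyses and both share the 50% chance
level. Ties count as incorrect, so duplicated targets (e.g. zero
within-class jitter in the generator) depress the metric by construction.
Fold summaries are unweighted means over folds.

## The synthetic generator: what it emulates, and what it does not

No public accession exists for the kind of dataset the pipeline targets,
so `simulate_dataset()` defines a generative model with ground truth:

* class prototypes in feature space (`prototype_spread`, default 1),
  per-exemplar jitter (`within_class_jitter`);
* `y1 = A y0 + noise` for a fixed random linear map A, so the auxiliary
  loss is informative about the primary target;
* the readout stacks class prototypes as rows of W (zero bias): with zero
  jitter each prototype is its own nearest readout direction;
* each planted voxel responds as `gain_s · (w_v · y0) + run noise`, with
  encoding vectors `w_v` shared across subjects (entries of sd
  1/sqrt(d0), so signal variance ≈ prototype_spread² regardless of d0),
  multiplicative subject gains `gain_s ~ 1 + N(0, subject_gain_sd²)`, and
  iid Gaussian run noise; remaining voxels are pure noise.

This is deliberately the simplest structure under which reliability
selection is meaningful and PCA-plus-regression is consistent. The
expected split-half reliability has the closed form
r = s² / (s² + noise_sd²/(n_runs/2)), inverted by
`reliability_noise_sd()` to plant voxels at a chosen true reliability.

What the generator does **not** emulate: hemodynamics or time series
(betas only), spatial autocorrelation between voxels, nonlinear or
subject-specific encoding, misalignment across subjects, and
heavy-tailed noise. Consequently, passing tests demonstrate that the
pipeline's machinery is correct and recovers planted structure — not that
real cortical responses are linearly decodable at any particular accuracy.

## Packaged benchmarks and what the tests assert

`benchmark_config()` freezes four study conditions (problem sizes chosen
so the full suite runs comfortably on one CPU):

* **reliability** — 1 subject, 39 stimuli, 5,000 voxels with 500 planted
  at true reliability ≈ 0.7 (8 runs). The 0.3 cutoff must recover ≥ 95%
  of planted voxels with ≤ 5% false positives; both bounds follow from
  the sampling distribution of r over 39 stimuli.
* **decoding** — 13 subjects, 39 categories, high SNR (run noise 0.3,
  gain sd 0.1), 600 voxels / 250 planted. The multi-task MLP at 200
  epochs must reach ≥ 90% LOSO Top-1.
* **decoding_noise_free** — the identifiability limit (zero noise, zero
  gain spread): any consistent regressor reaches 100% Top-1.
* **ordering** — 8 subjects at low single-subject SNR (true single-subject
  reliability ≈ 0.25; the group-averaged map used for selection remains
  reliable), where augmentation and voxel-coverage effects are visible.

Two honest limitations of benchmark-based qualitative comparisons are
worth stating plainly, because they are properties of the generator, not
bugs:

* **Ridge is hard to beat here.** The planted encoding is *linear*, so
  ridge regression is the correctly-specified estimator; at every noise
  level we examined it matches or exceeds the MLPs on held-out subjects.
  The regressor-quality ordering (multitask MLP ≥ plain MLP ≥ ridge ≥
  KNN, pairwise metric) is therefore asserted on the high-SNR benchmark,
  where the first three saturate the identification metric and KNN falls
  measurably short. On real, nonlinearly-encoded data the MLPs' advantage
  has substance; a linear simulator cannot manufacture it.
* **Fewer voxels can help weakly regularized models.** Restricting to an
  ROI shrinks the input dimension, which acts as implicit regularization
  for ridge (small α) and speeds MLP convergence at a fixed epoch budget —
  occasionally *raising* Top-1. The broader-coverage-is-better comparison
  (whole-brain reliable vs. single ROIs) is therefore asserted on the
  identification metric, which tracks information content more directly.

## Reproducibility

Every stochastic step is seeded: the generator from its config seed (via
two derived streams for feature space and betas), each LOSO fold from the
regressor seed and fold index, and augmentation from its own seed and
fold index. Derived seeds stay below 2^31. Identical configuration and
seed give bit-identical datasets, loss traces (to floating-point
determinism on one platform) and summaries; the command-line wrapper
writes a reproducibility manifest (config, seed, package versions) with
every run.

## Known limitations

* No hemodynamic modelling, GLM fitting, registration or brain
  visualization; inputs are beta matrices (plain-text bundle or NIfTI).
* The MLP trains on CPU in plain R; it is sized for hundreds of samples
  and ~1,000 inputs, not for orders of magnitude more.
* The permutation/chance machinery covers Top-k and pairwise nulls only;
  no further significance testing is provided.
* Cross-set reliability assumes category-matched exemplars across the two
  video sets; other pairing conventions are not supported.
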