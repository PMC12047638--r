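---
title: "Methods: cross-participant searchlight RSA, decoding, and TFCE inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-participant searchlight RSA, decoding, and TFCE inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslight)
```

## The scientific problem

In studies of conscious and unconscious vision, participants discriminate
briefly presented, masked images and rate their awareness on every trial
(no experience / brief glimpse / clear experience). The question this
package's pipelines address is representational: does a model of the
stimulus — here, hidden-layer features of a convolutional network — predict
the multivoxel BOLD response to those stimuli, does that predictive
relationship hold on trials the observer reports *not* seeing, and is the
representation shared across brains? Because all subjects' data live on one
standardized grid, models can be fitted on one subject and tested on
another; each ordered subject pair yields an independent whole-brain map,
and the pairs form the units of a group-level permutation test.

## Pipelines

### Encoding-based searchlight RSA

For a subject pair (train → test) and a scenario (within-conscious,
within-unconscious, or conscious→unconscious):

1. **Encoding fit.** Every voxel's response is regressed on the item's
   feature vector with a shared ridge penalty. Features are standardized
   with training statistics (frozen thereafter); responses are not. The fit
   is whole-brain and closed-form: for voxel-separable linear models, fitting
   once and slicing predictions per sphere is mathematically identical to
   per-sphere fitting, and much cheaper.
2. **Prediction and summarization.** The model predicts responses for the
   item set the test subject actually saw in the test condition; the test
   subject's observed trial responses are averaged by item (the same
   summarization applied to network features). If stochastic awareness
   labels leave some items unseen in a condition, that pair's RDM shrinks to
   the covered item set and the reduction is logged.
3. **Searchlight comparison.** At each in-mask center, the predicted and
   observed item × item RDMs over the sphere's voxels (1 − Pearson) are
   compared by Spearman correlation of their strictly-lower triangles;
   ρ is written to the center.

### Cross-participant searchlight decoding

Per sphere: a per-feature standardizer (means and standard deviations from
the training subject only, locked at test) followed by an L1-regularized
linear SVM classifies animate vs inanimate; the held-out subject's trials
are scored by ROC AUC from the continuous decision values. Hard labels
would degenerate the ROC curve to a single point, so decision values are
used throughout. The L1 penalty sets uninformative voxel weights exactly to
zero, an embedded feature selection.

### Group inference

Per scenario, the stack of pair maps is tested one-sided against its chance
level (0 for ρ; 0.5 for AUC) by sign-flip permutation on the TFCE transform
of the mean map, with familywise correction from the permutation
distribution of the image-wide maximum. Sign flipping implements the
one-sample test under the assumption that pair maps are exchangeable and
symmetric about the null value when no effect exists. The pair maps share
subjects, so they are not independent; treating them as exchangeable units
is inherited from the cross-participant design itself and is not corrected
here.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `radius_mm` | 6 | mm | Classic searchlight radius; equals a 3-voxel sphere at 2 mm isotropic voxels. Radius is specified in millimeters and converted through the voxel size, honoring both conventions; a voxel-unit override exists in the CLI. |
| `regularization_strength` | 1 | — | Ridge penalty on standardized features; keeps the solve stable when trials are few relative to features. Predictions shrink to the per-voxel training mean as it grows. |
| `penalty_strength` (C) | 1 | — | Inverse L1 regularization of the SVM (penalty = 1/C). At C = 1, toy experiments in the test suite show the selected voxel set concentrating on the planted informative voxels. |
| `height_exponent`, `extent_exponent` | 2, 0.5 | — | Field-standard TFCE constants. |
| `dh` | max/100 | statistic units | Staircase integration step; 100 steps reproduce an isolated voxel's closed form v³/3 within 2%. |
| `connectivity` | 26 | — | Corner-sharing neighborhood, the common volumetric default (6 and 18 available). |
| `n_permutations` | 5000 | — | Sign-flip draws; all 2ⁿ − 1 non-identity patterns are enumerated instead whenever that is fewer, making the test exact. |

## The synthetic generator

The generator realizes the design of the reference experiment as its
defaults: 7 subjects; 96 items, half animate, presented in 6 sessions × 9
blocks × 32 trials (288/session, 1728/subject) with items balanced up to
rounding; per-trial awareness drawn i.i.d. from (0.45, 0.10, 0.45) over
unaware/glimpse/aware. Item features (default 300-dimensional) are sampled
with equicorrelated rows within each category, planting the animate /
inanimate block structure that network RDMs show; feature dimensions are
unit-variance so the encoding weights (entries ~ N(0, 1/dim)) give
unit-variance voxel signals and `noise_sd` reads as an inverse
signal-to-noise ratio. Inside a designated signal region each voxel's trial
response is its subject's linear map applied to the trial's item features
plus Gaussian noise; all other in-mask voxels are pure noise. Per-subject
weight maps mix a common and an idiosyncratic component as
`sqrt(f)·W_common + sqrt(1−f)·W_subject`, so `shared_fraction = 1` is a fully
shared representational blueprint and 0 is fully idiosyncratic.

What the generator does **not** emulate: hemodynamics and time-series
structure (volumes are trial-level response maps, sidestepping the question
of how single-trial responses were estimated from raw series), the adaptive
staircase coupling stimulus duration to awareness (only the labels matter
downstream), spatial autocorrelation of fMRI noise, and nonlinear or
rotated-but-equivalent representational geometries. Passing recovery tests
therefore demonstrates the pipeline's correctness and calibration under a
linear, voxelwise-independent world — not that real cortex behaves this way.

Behavioral responses are generated with awareness-dependent accuracy
(default 0.5 / 0.75 / 0.95 for unaware/glimpse/aware), so unaware-trial
sensitivity d′ ≈ 0 — the "null perceptual sensitivity" regime; `d_prime()`
and `subject_d_prime()` reproduce the subject-subset selection, and
scenarios accept a `subject_subset`.

## Numerical choices

- **Pearson / RDM**: centered cross-products with a 1e−12 variance guard;
  a zero-variance pattern row is a data error naming the item. Entries are
  symmetrized and clamped to a zero diagonal; values live in [0, 2].
- **Spearman**: average ranks for ties (the conventional definition); a
  constant lower-triangle vector yields `NA` with a warning rather than an
  arbitrary number.
- **ROC AUC**: Mann–Whitney rank form, ties counted ½; single-class test
  sets yield flagged `NA`.
- **Ridge solve**: Cholesky of the standardized Gram matrix plus the penalty;
  a 1e−10 jitter keeps the unpenalized limit solvable under collinearity and
  is dominated by any real penalty. Constant features pass through centered
  (they carry no signal either way).
- **L1 SVM**: FISTA with soft-thresholding, unpenalized intercept, step from
  a power-iteration bound on the Lipschitz constant, objective-change
  stopping at 1e−4 (checked every 10 iterations, 500-iteration cap). The
  solver is deterministic; the `seed` argument exists for interface
  stability only.
- **d′**: log-linear correction (0.5 to every cell) applied only when a hit
  or false-alarm rate is exactly 0 or 1; interior rates are used as-is.
- **TFCE**: descending-threshold incremental union-find in C++; per-image
  `dh = max/100` unless pinned. Note the staircase with adaptive `dh` is
  monotone only up to discretization: raising a voxel changes the grid.
  Property tests of monotonicity pin `dh`.
- **Permutation p-values**: `(1 + #{max ≥ t}) / (n_used + 1)` for sampled
  flips; for exhaustive enumeration `n_used = 2ⁿ − 1` non-identity patterns,
  so the identity is counted exactly once and min p = 1/2ⁿ.
- **Searchlight edges**: spheres truncate at the mask (no padding), always
  contain their center, and an optional minimum-voxel threshold can blank
  undersized spheres. A statistic error at one center records `NA` plus one
  summary warning instead of aborting the map; a validity mask accompanies
  every map and group inference restricts itself to voxels valid in all maps.

## Design choices where the ground was open

- **Encoding estimator**: ridge regression with a single shared penalty,
  solved in closed form — the standard, deterministic choice for voxelwise
  encoding; no per-voxel hyperparameter search.
- **BOLD responses are not standardized** before fitting (flagged default).
- **Features post-activation**: extracted features are the hidden layer's
  SELU outputs.
- **Head training**: one-vs-all binary cross entropy over one-hot targets
  with full-batch SGD and patience-5 early stopping on a 25% validation
  split; the convolutional backbone stays frozen. The package trains this
  head only at toy scale — large-scale network fine-tuning is out of scope,
  and any trained backend can be plugged in via `register_backbone()`.
- **Group statistic**: TFCE of the mean map (not a t-map), 5000 default
  permutations; both logged in run manifests.

## Scales used by the test suite

Tests and the acceptance script run at desk scale: grids of 6³–12³ for unit
and calibration tests; the end-to-end recovery test uses the default 24³
grid with 4 subjects, 12 items, 72 trials/subject, and 1000 permutations;
familywise error calibration uses 60 zero-signal replicates of a 9³ study
with 500 permutations each. These sizes are the package's chosen test
scale; all methods accept full-size inputs (96 items, 1728 trials, MNI-like
grids) through the same interfaces.

## Known limitations

- Only the 1 − Pearson dissimilarity and Spearman RDM comparison are
  implemented; Euclidean, Mahalanobis, Riemannian and shape-metric
  geometries are extension points.
- Linear encoding and decoding only; no nonlinear kernels or response
  functions.
- Inputs must share one grid; registration to standard space happens
  upstream.
- The exchangeability of subject-pair maps (which share subjects) is
  assumed, as in the cross-participant design this package implements.
- Class imbalance in decoding conditions is logged, not corrected.
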