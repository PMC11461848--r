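---
title: "Methods: deep 3D feature fusion and whale-optimized feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep 3D feature fusion and whale-optimized feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

`neurofuse` implements a hybrid classification framework for three-class
volumetric brain MRI (control, prodromal, Parkinson's disease). The pipeline
has four model variants of increasing complexity:

1. **Model 1** — a seven-convolution 3D CNN ("variant 3" of an ablation
   series) is trained on preprocessed volumes; its two 1000-unit fully
   connected layers are tapped (`FC1`, `FC2`), merged element-wise by
   maximum into `FC3`, and classified with a classical learner.
2. **Model 2** — the same with a fifteen-layer residual 3D network, tapped
   at its 1000-unit fully connected layer (`FC4`).
3. **Model 3** — `FC3` and `FC4` (2000 features total) are fused by
   regularized canonical correlation analysis (CCA) into canonical
   discriminant features `Z1` (concatenated variates) or `Z2` (summed).
4. **Model 4** — the fused features are pruned by whale-optimization (WOA)
   wrapper feature selection with a KNN-error fitness before
   classification.

Every stage is driven by explicit config objects and a single master seed,
and every stage can be exercised on synthetic data, because the clinical
MRI repository this design targets is access-gated.

# Preprocessing contract

Real volumes arrive as DICOM slice series or NIfTI-1 files.
`preprocess_volume()` trilinearly resamples to the network input size
(56×56×56 by default) and z-scores intensities over the volume; constant
volumes map to zeros rather than dividing by zero. Skull stripping and
bias-field correction are deliberately **not** reimplemented — they are
external published tools, and volumes are expected to be pre-cleaned
upstream. Trilinear interpolation and z-scoring (rather than min–max) are
package choices; the upstream description does not fix either. Slice
stacks are ordered by the projection of ImagePositionPatient on the slice
normal, ties broken by InstanceNumber.

# Extractor architectures

The exact convolution hyperparameters of the source architectures are not
published; the package freezes one concrete enumeration and exposes tap
points by name so no caller depends on raw layer indices:

* **CNN variant 3**: blocks of 2, 3 and 2 convolutions (3×3×3 kernels,
  ReLU), each block closed by 2×2×2 max pooling and batch normalization;
  filter widths `base_width`·(1,1 | 2,2,2 | 4,4), default `base_width =
  32`; global max pooling; dense 1000 (`FC1`), dense 1000 (`FC2`); softmax.
* **ResNet-15**: two initial conv+BN+ReLU blocks, then five residual
  stages of three units each — every unit is conv-BN-ReLU-conv-BN-ReLU
  with a skip connection added after the final ReLU, with a 1×1×1
  projection when the channel count changes — each stage followed by max
  pooling; then dense 1000 (`FC4`) and softmax. Counting input, the two
  conv blocks, the five stage/pool pairs, the fully connected layer and
  the softmax gives the fifteen named layers.

Training uses softmax cross-entropy, Adam (default) or SGD, L2 weight
decay 1e-4, 30 epochs, learning rate 1e-3 (CNN) or 1e-4 (ResNet), a
stratified 70/15/15 split, early stopping on validation loss with
patience 5, and returns the best-validation checkpoint. Two numerical
choices matter in practice and are package decisions:

* the loss is computed from the logits by log-sum-exp (a clamped
  `log(probability)` plateaus once the softmax saturates, which breaks
  gradient checking and stalls recovery from bad initialization);
* the closing batch-norm gain of every residual unit is initialized to
  0.1 instead of 1 — fifteen stacked additive skips otherwise blow up the
  forward signal at initialization and saturate the head. Exactly zero
  (the common "zero-init residual" trick) is *not* usable here because the
  unit ends in a ReLU: a zero gain would make that ReLU's input exactly
  zero and permanently block the gain's own gradient.

Tests and the acceptance suite shrink `base_width` (to 2–4) and the input
size (28³ or 16³) together; the architecture — counts, grouping, tap
widths — is unchanged by this scaling.

# Element-wise maximum merge

`fc_concat_max(FC1, FC2)` merges the CNN's two 1000-vectors position-wise
by taking the larger value; equal values are taken once, so nothing is
duplicated and the output length stays 1000. This is a fixed, parameter-free
merge; stacking it with the ResNet's `FC4` gives the 2000-feature budget
that fusion consumes.

# CCA fusion

With views A (n×p) and B (n×q), column-centered, the canonical directions
solve `S_AA^{-1} S_AB S_BB^{-1} S_BA w_A = ρ² w_A`. In the deep-feature
regime (p = q = 1000, n a few hundred) the within-view covariances are
singular, so they are shrunk to `S + λ·tr(S)/p·I` (default λ = 1e-3), and
an optional per-view PCA pre-reduction to rank ≤ n−1 is available for
speed; returned transformation matrices are always composed back to the
original feature space. Canonical correlations are clamped to [0, 1];
variates are scaled to unit training variance. `d` defaults to the number
of correlations above 1e-6.

Sign conventions: the first nonzero loading of each `W_A` column is made
positive, and the matching `W_B` column's sign is then chosen so the
canonical correlation is nonnegative. Forcing the first-loading rule on
*both* matrices (an earlier design idea) can flip a correlation negative,
which contradicts the `[0, 1]` invariant; the asymmetric rule is just as
reproducible and keeps the invariant.

`Z1` (concatenation, width 2d) is the default selection input; `Z2`
(summation, width d) is available by config. Concatenation preserves more
information and is the documented default because the upstream description
does not state which variant fed selection.

# Wrapper feature selection

Masks are scored by `f = α·err + (1−α)·|R|/N` with α = 0.99, where `err`
is the error of a KNN classifier (k = 5) restricted to the masked
columns. Two design points deserve an explanation:

* **Error estimate.** The package default is a stratified 5-fold
  cross-validation error with one fixed, seeded fold assignment per
  optimizer run (`fitness_spec(cv_folds = 5)`); a single fixed 80/20
  split (`cv_folds = 1`) is available. The single-split variant was the
  original design, but with n = 300 its 60-sample validation set
  quantizes the error at 1.7% steps: five-feature masks that memorize the
  split reach zero validation error, so the optimum of the fitness is a
  split-overfit micro-mask rather than the truly informative subset. We
  verified this directly with exhaustive greedy search — under the
  single split the greedy optimum on planted problems kept 4–8 features
  of which up to half were noise. The cross-validated error keeps the
  landscape deterministic within a run while resolving marginals at
  1/n, and the greedy optimum then coincides with the planted subset.
* **Search geometry.** Positions live in [0, 1]^N and are thresholded at
  0.5 into masks (ties select). The WOA coefficients `A` and `C` are
  drawn per dimension, as in the reference implementation of the
  algorithm; with scalar draws the swarm mixes far too little to search
  a combinatorial space. WOA's contraction is aggressive — the swarm
  typically coincides with the incumbent within ~50 iterations and is
  then frozen under deterministic thresholding — so independent restarts
  (the published search settings use 20) are the essential diversity
  mechanism, and `woa_select()` returns the best mask across restarts.

The empty mask scores 1.0 (worst) by convention, keeping the fitness a
total function. GA and ACO baselines operate natively on bit strings; PSO
and GSA share the continuous box and threshold with WOA. All baselines
run under the identical fitness and budget, and every optimizer's
best-so-far curve is non-increasing by construction (elitism).

One further reading note: the upstream description writes the encircling
update with an outer absolute value and uses two different symbols for
the stochastic coefficient; the canonical formulation (no outer absolute
value, independent `A` and `C` coefficients) is implemented, as the text's
own branch equation restates the update in canonical form.

# Synthetic worlds, and what a green test establishes

**Phantoms.** Volumes contain a bright brain-like ellipsoid plus a small
nucleus-like region whose intensity (+0.5 common contrast plus per-class
deltas, default 0, 0.45, 0.9) and radii (scale 1, 1.12, 1.24) differ by
class, with optional center jitter and white Gaussian noise. Classes
differ only locally — a deliberate echo of subcortical signal change — so
extractors must learn localized features. The "easy" worlds the tests
lock: 28³, noise 0.05, deltas (0, 0.6, 1.2) for extractor sanity; the same
at 16³ with n = 30 for the end-to-end run. The phantoms do not emulate
MRI physics, bias fields, anatomy, or scanner variability; a green
end-to-end test establishes that the pipeline's stages compose and learn
localized synthetic contrast, not clinical performance.

**Dual-view generator.** `A = z Λ_A' + ε`, `B = z Λ_B' + ε` with shared
latent z, orthogonal loading columns of norm `s_j = scale/√j`, isotropic
noise σ. The population canonical correlations are
`ρ_j = s_j²/(s_j²+σ²)` in closed form, which makes CCA estimation
testable against ground truth.

**Planted selection problems.** Balanced labels; informative columns are
unit-variance Gaussians whose class-conditional means follow a rotating
`effect_size·{−1, 0, +1}` pattern so each informative feature separates
one class pair with equal strength; the posterior `P(y | x_S)` is then
exactly multinomial-logistic (the equal-covariance Gaussian / logistic
equivalence). An earlier design thresholded a single rank-one logit into
tertiles, but a rank-one signal spread over ten features is nearly
invisible to Euclidean KNN (even the oracle subset left ~40% error), so
recovery tests built on it measure nothing; the rotating-mean construction
keeps the "logistic rule, informative only through S" semantics while
making the subset genuinely recoverable. Noise columns have sd 2 — at
equal scale, irrelevant features cost a KNN wrapper almost nothing
individually, and selection pressure vanishes. The locked recovery world:
n = 300, N = 100, k = 10, effect 0.9, noise sd 2.

# Numerical and procedural choices

* All generators and training loops draw randomness under a locally set,
  restored seed — no global RNG state leaks; a single master seed fans
  out to per-stage seeds by a fixed affine rule.
* Distance ties in KNN resolve to the lower row index, vote ties to the
  smaller class label; tree vote ties likewise — all deterministic.
* Macro averaging is the default for precision/recall/F1 (unweighted
  across the three classes); weighted averaging is a config option.
  Classes never predicted contribute precision 0 with a warning.
* The "SVM" classifier is a least-squares SVM (RBF kernel ridge,
  one-vs-rest): no quadratic-programming SVM library is available in the
  target environment, and the LS-SVM is the closest well-defined
  formulation. KNN, CART trees (bagged into a random forest; boosted with
  multinomial-deviance gradient boosting, Friedman leaf updates) are
  implemented in compiled code.
* Pooling floors odd dimensions (28 → 14 → 7 → 3); axes already at size 1
  pass through pooling unchanged, so deep pooling schedules remain valid
  at small test resolutions.

# Known limitations

* Training budgets at desk scale are tiny (tens of volumes, widths 2–8);
  the deep extractors demonstrably learn the synthetic contrast but no
  claim about clinical MRI transfer is made or testable here.
* The planted-subset recovery criterion is sensitive to the interaction
  of KNN geometry, validation granularity and WOA's early swarm
  collapse; the locked world passes under cross-validated fitness with
  restarts, and the limits of the single-split variant are documented
  above rather than hidden.
* The DICOM reader handles uncompressed little-endian single-frame
  grayscale series only — the subset its own writer emits and the subset
  the pipeline needs.
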