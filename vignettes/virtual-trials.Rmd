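---
title: "Virtual interventional trials: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual interventional trials: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inferential problem

Individualized prescription asks: given this patient's lesion, which of two
treatments gives the better expected outcome? Under the Neyman–Rubin
potential-outcomes model each patient has two potential outcomes, one per
arm, but any real trial reveals only one. A prescriptive model can
therefore never be audited patient-by-patient on real data. The framework
in this package makes the audit possible by *constructing* the missing
counterfactual: cohorts are simulated with a known per-patient optimal
treatment, trials are simulated on top of them, and models are scored
against the hidden truth.

The target quantity is the conditional average treatment effect,

$$\tau(x) = P(Y = 1 \mid W = A, x) - P(Y = 1 \mid W = B, x),$$

estimated by an S-learner (one outcome classifier over `[x, 1(W = A)]`) or
a T-learner (one classifier per arm). The prescription is the arm with the
larger predicted outcome probability, ties going to A deterministically.

## The generative model

### World and maps

`generate_world()` builds an ellipsoidal grey-matter mask on a cubic voxel
grid and partitions it into `n_networks` contiguous functional networks by
simultaneous breadth-first growth from random seed voxels over
6-connectivity. Contiguity is guaranteed by construction; each network is a
single connected cell, mirroring the spatial coherence of real functional
parcels. Geometric vascular atlases (anterior/posterior with and without
laterality, and a 6-wedge fine atlas) stand in for arterial-territory
atlases.

Three families of synthetic maps give the world a recoverable latent
structure:

- **Term maps** (`generate_term_matrix()`): each meta-analytic "term"
  belongs to one network and scores `effect` on that network's voxels plus
  Gaussian noise. Clustering voxel columns by correlation distance
  recovers the planted partition — exactly at zero noise (an acceptance
  oracle) and at the default noise level 0.1 in practice.
- **Receptor z-maps** (`generate_receptors()`): independent smoothed
  Gaussian random fields standardized over the grey mask, emulating
  group-average PET z-score maps. Smoothing induces the spatial
  autocorrelation that makes receptor preponderance well-defined.
- **Transcriptome samples** (`generate_transcriptome()`): per network,
  sample sites with a planted two-way split aligned with a spatial half of
  the network; expression profiles are split-specific mean shifts plus unit
  noise, so two-way clustering of profiles recovers the split.

### Lesions, tracts, disconnectomes

Lesions are grown by stochastic region growing inside the grey mask from a
seed voxel (optionally biased by a frequency map), with a uniform target
size. They are connected by construction and respect tissue boundaries —
the two properties of real stroke lesions that matter for this framework
(spatial coherence and anatomical plausibility); vascular-topology realism
is out of scope. Surrogate tract bundles are guided random-walk voxel paths
between grey-matter endpoints with per-subject directional jitter. The
probabilistic disconnectome of a lesion is the proportion of reference
subjects for whom some bundle intersects the lesion, accumulated over each
intersecting bundle's full voxel support, with lesion voxels set to 1 by
convention. Only this output contract matters downstream; the walk model
itself is deliberately minimal.

### Ground truth

Each functional network is split into two treatment-responsive subnetworks:

- **Receptome criterion**: receptor preponderance is the Dice coefficient
  between the network mask and each receptor map binarized at `z > 0`; the
  two most preponderant receptors are selected and every network voxel is
  assigned to the one with the greater z there.
- **Transcriptome criterion**: in-network sample sites are two-way
  clustered on expression profiles; each cluster's site indicator is
  Gaussian-smoothed at bandwidths from a grid, voxels take the cluster with
  the greater smoothed value, and the bandwidth minimizing
  $J(\sigma) = |n_A - n_B|/(n_A + n_B) + \lambda(\text{components} - 2)$
  is retained ($\lambda = 0.05$), balancing class balance against spatial
  fragmentation.

A patient is *responsive* to a treatment iff their designating mask (the
lesion, or the disconnectome binarized strictly above 0.5) covers strictly
more than 5% of the corresponding subnetwork's volume. Patients responsive
to neither arm are excluded; dual responders (`s = 0`) are retained, enter
PEHE, and are excluded from balanced accuracy. The true individual effect
is `τ = s · (TE − RE)` (effect-scaled; a sign-scaled alternative is
available).

### Trials

Outcomes follow the treatment-effect/recovery-effect noise model: a
favourable outcome is drawn with probability `TE` when the allocated arm
suits the patient (`w = w*`, or `w* = "either"`), else `RE`. `TE = 1, RE =
0` is the noiseless endpoint at which prescriptive inference must be exact.
An alternative immune-or-responder composition
(`Y = I ∨ (R ∧ suitable)`) is available behind `noise_config(model = "or")`.

Allocation policies:

- **Randomized** — equivalent to observable confounding at `b = 0`.
- **Observable** — patients are ranked by lesion centroid along the axis
  of maximal subnetwork-centroid separation; for `b ≤ 0.5` the probability
  of arm B for rank *k* is the *k*-th element of
  `linspace(0.5 − b, 0.5 + b, N)`. For `b > 0.5` a per-tail fraction
  `f = b − 0.5` of ranked patients is allocated deterministically by their
  side of the training-fold median — rank *k* is deterministic iff its
  midpoint `(k − 0.5)/N` lies within `f` of either end — and interior
  ranks get probabilities evenly spaced over `[0, 1]`. The midpoint rule
  makes the regime continuous at `b = 0.5` and fully deterministic at
  `b = 1` for every cohort size.
- **Unobservable** — `W = w*` with probability `b`, else the other arm;
  dual responders get a fair coin. At `b = 0.5` allocation is independent
  of the truth.

### Representations and learners

Lesion phenotypes of increasing expressivity: one-hot vascular-territory
codings (the territory with maximal Dice overlap), PCA, NMF
(multiplicative Lee–Seung updates), and small fully connected standard and
variational autoencoders, all fitted on training-fold volumes only.
Oracle features `x = (r_A, r_B)` expose the truth directly for diagnostic
conditions. Base classifiers: extremely randomized trees, random forests,
gradient-boosted trees, logistic regression, Gaussian processes (with a
seeded subsample cap), and an exact lookup-table estimator used as a test
oracle.

### Evaluation

Patient-grouped k-fold cross-validation (folds fixed before any fitting);
balanced accuracy over single responders; PEHE
$\sqrt{\tfrac{1}{N}\sum(\hat\tau - \tau)^2}$ over all validation records;
pooled-variance t-tests with Cohen's d; Benjamini–Hochberg step-up FDR
control. Degenerate folds (an empty arm, or single-class outcomes overall
or within an arm for the T-learner) are marked and carry no metrics.

## Numerical and implementation choices

- **Seeding.** Every stochastic stage derives its own seed as
  `derive_seed(master, key)`, a 32-bit polynomial rolling hash of a
  human-readable key mixed with the master seed, always in
  `[1, 2^31 − 2]`. Any grid cell replays bit-exactly in isolation.
- **Tree learners grow to purity.** Probability forests default to
  `min.node.size = 1` and `mtry = `all features. The latter matters for
  exactness: with random feature subsetting, a node whose drawn feature is
  constant becomes terminal while still impure, and forest-averaged
  probabilities are then fractional even on noiseless separable data. Both
  are overridable per learner.
- **NMF and autoencoders are implemented in-package** (multiplicative
  updates; manual backprop with Adam, batch size 10, 16–32 epochs, early
  stopping after 4 flat epochs). The autoencoders are fully connected
  rather than convolutional: no R deep-learning backend is assumed, and
  PCA/NMF are the always-available representation methods on which all
  exactness guarantees rest. VAE embeddings are posterior means, never
  samples, so embedding is deterministic.
- **PCA** uses `stats::prcomp` with zero-padding when the requested
  dimensionality exceeds the training rank, so phenotypes always have the
  configured length.
- **Strict thresholds.** Disconnectome binarization (`> 0.5`) and
  responsiveness designation (`> 0.05`) are strictly greater-than;
  boundary cases are excluded by definition, making the ground truth
  insensitive to representation-independent ties.
- **Smoothing** is separable Gaussian convolution truncated at 3σ with
  zero padding; component analysis uses 26-connectivity flood fill
  (6-connectivity available).
- **Gaussian smoothing, clustering, linkage**: correlation distance with
  average linkage via `stats::hclust`; small parcellation islands
  (< 64 voxels at study scale) are dissolved into the majority label of
  their 5 nearest non-island voxels.

## Scale accounting

The full-scale study enumerates 16 networks × 2 responsiveness criteria ×
2 lesion-representation kinds × 4 TE × 4 RE × 22 allocation policies =
22,528 conditions, each crossed with 46 representations (2 atlas baselines
+ 11 dimensionalities × 4 methods) × 10 meta-learner/classifier pairs =
460 configurations, under 10-fold cross-validation: 103,628,800 fold-level
simulations (`study_scale_accounting()`). The package reproduces this
accounting exactly and runs reduced grids with the same machinery; the
full grid is out of desk scope by design.

## Limitations

- The synthetic world is geometric, not anatomical: no hemispheric
  asymmetry beyond the atlas construction, no white/grey distinction
  beyond the mask, no vascular topology in lesion growth.
- Surrogate tracts share only the output contract with tractography;
  disconnectome values are step-like at small reference-subject counts.
- The autoencoders are small MLPs; representational conclusions about
  *convolutional* encoders do not transfer.
- The deterministic-extremes fraction for observable confounding beyond
  `b = 0.5` is a documented surrogate (the fraction is not uniquely
  determined by the trial-design description it implements).
- Headline comparisons at desk scale use hundreds of patients and a
  handful of seeds; effect sizes are stable in sign but not in magnitude
  across scales.

## Reproducing the numbers

All empirical claims in the README are produced by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`:

```{r}
# from the repository root, with the package installed:
testthat::test_dir("tests/testthat", package = "vitrials",
                   load_package = "installed")
```

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
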