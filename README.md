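# vitrials

Semi-synthetic **virtual interventional trials** for individualized
prescriptive inference in ischaemic stroke.

Real interventional data cannot tell us whether a model that prescribes
treatments *individually* is right, because each patient reveals only the
outcome of the one treatment they received. `vitrials` sidesteps this by
simulating two-arm trials on cohorts whose ground truth is fully known: a
synthetic brain carries functional networks split into two
treatment-responsive subnetworks, each lesion deterministically fixes which
treatment (if either) the patient responds to, and observed outcomes are
then sampled under controllable noise and allocation bias. Prescriptive
models see only the lesions, the allocations, and the outcomes — never the
truth — so their individualized prescriptions and treatment-effect estimates
can be scored exactly.

## What the framework does

1. **Synthetic cohort** — an ellipsoidal grey-matter grid with planted,
   contiguous functional networks; meta-analytic term maps, receptor
   z-maps, and transcriptome sample sites with planted structure; stochastic
   region-grown lesions; surrogate tract bundles and probabilistic
   disconnectome maps.
2. **Parcellation** — agglomerative clustering of voxel association
   profiles (correlation distance, average linkage), small-island cleanup,
   term ranking.
3. **Ground truth** — each network is subdivided into subnetworks A and B
   by receptor preponderance (Dice, top-2 receptors, per-voxel argmax z) or
   transcriptome clustering (two-way clustering of expression profiles,
   smoothed spatial assignment). A patient responds to a treatment iff their
   lesion (or binarized disconnectome) covers strictly more than 5% of the
   corresponding subnetwork. This yields the hidden record
   `(r_A, r_B, s = r_A − r_B, w*, τ = s·(TE − RE))`.
4. **Trial engine** — treatment allocation that is randomized, observably
   confounded on lesion location (rank-based linspace probabilities,
   deterministic extremes beyond `b = 0.5`), or unobservably confounded on
   the hidden optimal arm; outcomes sampled as `Bernoulli(TE)` when the
   allocated arm suits the patient and `Bernoulli(RE)` otherwise.
5. **Representations** — PCA, NMF, and (variational) autoencoder phenotypes
   of the lesion or disconnectome, vascular-territory one-hot baselines,
   and oracle features for diagnostics.
6. **Prescriptive inference** — S-/T-learner meta-learners over
   extremely-randomized trees, random forests, gradient-boosted trees,
   logistic regression, Gaussian processes, or an exact lookup oracle;
   CATE `τ̂(x) = P(Y=1|A,x) − P(Y=1|B,x)`; prescribe the argmax arm.
7. **Evaluation** — patient-grouped 10-fold cross-validation; balanced
   accuracy over single responders; PEHE including dual responders;
   pooled t-tests, Cohen's d, Benjamini–Hochberg FDR control.

At full scale the grid enumerates 22,528 trial conditions × 460
representation–learner configurations × 10 folds = **103,628,800
simulations** (see `study_scale_accounting()`); this repository runs
reduced, desk-scale grids with identical machinery.

## Worked example

```r
library(vitrials)

world <- generate_world(grid_spec(c(16, 16, 16)), n_networks = 4, seed = 1)
world
#> <brain_world> grid 16x16x16 | 1328 grey voxels | 4 planted networks | seed 1

receptors <- generate_receptors(world, n_receptors = 4, seed = 3)
pair <- subdivide_receptome(network_mask(world, 2), receptors, network_id = 2)
pair
#> <subnetwork_pair> network 2 | receptome | 422 + 282 voxels | receptor2 vs receptor3

lesions <- generate_lesions(world, n_patients = 150,
                            size_range_vox = c(15, 60), seed = 5)
input <- prepare_trial_input(lesions, pair, world, "lesion")
table(input$records$s)
#> -1  0  1
#> 26  7 26

folds <- make_folds(input$records$patient_id, k = 10, seed = 2)

# a confounded trial scored with 10-d PCA lesion phenotypes
cond <- trial_condition(TE = 0.9, RE = 0.1,
                        policy = list(kind = "observable", b = 0.8),
                        representation = list(type = "embedding",
                                              method = "pca", d = 10),
                        learner = list(kind = "T",
                                       algorithm = "extremely_randomized_trees"))
res <- run_condition(input, cond, folds, master_seed = 11)
round(mean(res$balanced_accuracy, na.rm = TRUE), 3)
#> [1] 0.723
round(mean(res$pehe, na.rm = TRUE), 3)
#> [1] 0.657

# the 2-territory vascular baseline in a fully randomized trial
cond_base <- trial_condition(TE = 0.9, RE = 0.1,
                             policy = list(kind = "randomized", b = 0),
                             representation = list(type = "baseline",
                                                   atlas = "two"),
                             learner = list(kind = "T",
                                            algorithm = "extremely_randomized_trees"))
res_base <- run_condition(input, cond_base, folds, master_seed = 11)
round(mean(res_base$balanced_accuracy, na.rm = TRUE), 3)
#> [1] 0.613
```

Even with strong observable confounding (`b = 0.8`), the expressive PCA
phenotype out-prescribes the atlas baseline running in a perfectly
randomized trial — the framework's central qualitative finding. At the
larger scale used by the acceptance suite (24³ world, 400 patients, 5
master seeds) the contrast is 0.768 vs 0.500 mean balanced accuracy.

## Repository layout

- `R/` — the package: all computation lives here.
- `analysis/` — numbered workflow drivers; run from the repo root in order:

  ```sh
  Rscript analysis/01_simulate_world.R   # world, maps, lesions, tracts
  Rscript analysis/02_parcellate.R       # functional parcellation + rankings
  Rscript analysis/03_ground_truth.R     # subnetwork pairs + hidden records
  Rscript analysis/04_run_trials.R       # the virtual-trial grid
  Rscript analysis/05_report.R           # summaries, contrasts, accounting
  ```

  All outputs land under `results/`; `analysis/config.yaml` controls every
  parameter and the master seed. The default desk-scale grid (16
  conditions × 4 configurations × 10 folds) completes in about 2 minutes.
- `tests/testthat/` — unit, property, and acceptance tests
  (`test-acceptance.R` holds one block per acceptance criterion).
- `scripts/acceptance.R` — standalone acceptance runner.
- `vignettes/virtual-trials.Rmd` — methods vignette: model, parameters,
  generator realism, numerical choices, limitations.

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "vitrials", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The full test suite runs in ~30 s; the acceptance script in ~15 s. With
`--seed 1` the acceptance run reports (among others)
`noiseless_mean_balanced_accuracy = 1`, `noiseless_mean_pehe = 0`,
`parcellation_agreement = 1`, `headline_gain ≈ 0.256`, and the study-scale
accounting `22528 × 460 × 10 = 103628800`. Every quantity is a pure
function of `--seed`; rerunning with the same seed is bit-identical.

## Design notes

- Determinism: every stochastic stage draws its own seed via
  `derive_seed(master, key)` (a documented 32-bit hash, always `< 2^31`),
  so any grid cell replays in isolation.
- Fold hygiene: embedders are fitted on training-fold volumes only; the
  observable-confounding median is computed on the training fold.
- Degenerate cells (an empty arm or single-class outcomes) are marked and
  excluded from averages rather than imputed.
- See `vignettes/virtual-trials.Rmd` for the modelling rationale and the
  full list of documented design decisions and limitations.
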