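#!/usr/bin/env Rscript
# Stage 4: run the configured virtual-trial grid (networks x rep kinds x
# TE x RE x policies, crossed with representation-learner configurations)
# under patient-grouped cross-validation.

source(file.path("analysis", "00_common.R"))

cfg <- load_config()
require_artifact(file.path(cfg$output_dir, "ground_truth",
                           "responsiveness_records.tsv"),
                 "03_ground_truth.R")
out <- file.path(cfg$output_dir, "trials")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

world <- build_world(cfg)
lesions <- build_lesions(cfg, world)
tracts <- build_tracts(cfg, world)

inputs <- list()
for (net in unlist(cfg$ground_truth$networks)) {
  pair <- build_pair(cfg, world, net)
  for (rk in unlist(cfg$grid$rep_kinds)) {
    inputs[[sprintf("net%d_%s", net, rk)]] <-
      prepare_trial_input(lesions, pair, world, rk,
                          tracts = if (rk == "disconnectome") tracts,
                          overlap_threshold = cfg$ground_truth$overlap_threshold)
  }
}

t0 <- proc.time()
grid <- run_grid(inputs,
                 TE_levels = unlist(cfg$grid$TE),
                 RE_levels = unlist(cfg$grid$RE),
                 policies = cfg$grid$policies,
                 configs = cfg$grid$configs,
                 k = cfg$grid$k_folds,
                 master_seed = derive_seed(cfg$master_seed, "study/trials"))
log_line("grid finished in", round((proc.time() - t0)[3], 1), "s")

write_tsv_atomic(grid$results, file.path(out, "results.tsv"))
acc <- grid$accounting
write_tsv_atomic(data.frame(quantity = names(acc),
                            value = unlist(acc)),
                 file.path(out, "accounting.tsv"))
log_line("accounting:", acc$conditions, "conditions x", acc$configs,
         "configs x", acc$folds, "folds =", acc$simulations, "simulations")
log_line("stage 4 complete:", out)
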