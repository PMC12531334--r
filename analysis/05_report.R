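#!/usr/bin/env Rscript
# Stage 5: summarize the virtual-trial grid — per-condition means, the
# representation-vs-baseline contrast (t-test, Cohen's d, Benjamini-Hochberg),
# a TE x RE x b pivot, and the study-scale accounting line.

source(file.path("analysis", "00_common.R"))

cfg <- load_config()
res_path <- require_artifact(file.path(cfg$output_dir, "trials",
                                       "results.tsv"), "04_run_trials.R")
out <- file.path(cfg$output_dir, "report")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

res <- read.delim(res_path, stringsAsFactors = FALSE)

cell_key <- c("input", "TE", "RE", "policy", "b", "representation", "d",
              "learner")
summ <- aggregate(cbind(balanced_accuracy, pehe) ~
                    input + TE + RE + policy + b + representation + learner,
                  data = res, FUN = function(v) mean(v, na.rm = TRUE),
                  na.action = na.pass)
degen <- aggregate(degenerate ~ input + TE + RE + policy + b +
                     representation + learner,
                   data = res, FUN = sum)
summ <- merge(summ, degen, by = setdiff(cell_key, "d"))
names(summ)[names(summ) == "degenerate"] <- "degenerate_folds"
# normal-approximation 95% CI across folds
ci <- aggregate(balanced_accuracy ~ input + TE + RE + policy + b +
                  representation + learner,
                data = res,
                FUN = function(v) 1.96 * sd(v, na.rm = TRUE) /
                  sqrt(sum(!is.na(v))),
                na.action = na.pass)
names(ci)[names(ci) == "balanced_accuracy"] <- "ba_ci95_halfwidth"
summ <- merge(summ, ci, by = setdiff(cell_key, "d"))
write_tsv_atomic(summ[order(summ$input, summ$TE, summ$RE, summ$b), ],
                 file.path(out, "condition_summary.tsv"))

# contrast each data-driven representation against the territory baseline
# within every condition cell, on fold-level balanced accuracies
reps <- setdiff(unique(res$representation), "baseline:two")
cells <- unique(res[res$representation == "baseline:two",
                    c("input", "TE", "RE", "policy", "b", "learner")])
contrasts <- list()
for (i in seq_len(nrow(cells))) {
  cell <- cells[i, ]
  sel_base <- res$representation == "baseline:two" &
    res$input == cell$input & res$TE == cell$TE & res$RE == cell$RE &
    res$policy == cell$policy & res$b == cell$b & res$learner == cell$learner
  base_ba <- res$balanced_accuracy[sel_base]
  base_ba <- base_ba[!is.na(base_ba)]
  for (rp in reps) {
    sel_rep <- res$representation == rp &
      res$input == cell$input & res$TE == cell$TE & res$RE == cell$RE &
      res$policy == cell$policy & res$b == cell$b & res$learner == cell$learner
    rep_ba <- res$balanced_accuracy[sel_rep]
    rep_ba <- rep_ba[!is.na(rep_ba)]
    if (length(rep_ba) < 2 || length(base_ba) < 2) next
    cmp <- compare_groups(rep_ba, base_ba)
    contrasts[[length(contrasts) + 1]] <-
      cbind(cell, representation = rp,
            mean_rep = mean(rep_ba), mean_base = mean(base_ba),
            t = cmp$t, p = cmp$p, cohens_d = cmp$cohens_d)
  }
}
contrasts <- do.call(rbind, contrasts)
contrasts$significant <- bh_adjust(contrasts$p, q = 0.05)
write_tsv_atomic(contrasts, file.path(out, "baseline_contrasts.tsv"))
log_line(sum(contrasts$significant), "of", nrow(contrasts),
         "representation-vs-baseline contrasts significant at FDR 0.05")

# heatmap-ready pivot: mean BA over inputs for each TE x RE x policy cell
pivot <- aggregate(balanced_accuracy ~ TE + RE + policy + b + representation,
                   data = res, FUN = function(v) mean(v, na.rm = TRUE),
                   na.action = na.pass)
write_tsv_atomic(pivot, file.path(out, "ba_pivot_te_re_b.tsv"))

# accounting: this run and the full-scale study
run_acc <- read.delim(file.path(cfg$output_dir, "trials", "accounting.tsv"))
study <- study_scale_accounting()
acc_df <- data.frame(
  scope = c(rep("this_run", nrow(run_acc)), rep("study_scale", 4)),
  quantity = c(run_acc$quantity, "conditions", "configs", "folds",
               "simulations"),
  value = c(run_acc$value, study$conditions, study$configs, study$folds,
            study$simulations))
write_tsv_atomic(acc_df, file.path(out, "accounting.tsv"))
log_line("study-scale accounting:", study$conditions, "x", study$configs,
         "x", study$folds, "=", study$simulations, "simulations")
log_line("stage 5 complete:", out)
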