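#' Patient-grouped cross-validation folds
#'
#' Random patient-level partition fixed before any model fitting; every
#' record of one patient shares a fold.
#'
#' @param patient_ids character vector (duplicates allowed).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return named integer vector mapping each unique patient id to a fold.
#' @export
make_folds <- function(patient_ids, k = 10, seed = 1) {
  ids <- unique(patient_ids)
  if (length(ids) < k) {
    stop("fewer distinct patients (", length(ids), ") than folds (", k, ")")
  }
  with_seed(derive_seed(seed, "folds"), {
    shuffled <- sample(ids)
    folds <- rep(seq_len(k), length.out = length(ids))
    stats::setNames(folds[match(ids, shuffled)], ids)
  })
}

#' Balanced accuracy of inferred prescriptions
#'
#' Restricted to single responders (`s != 0`); the mean of the per-class
#' proportions of correctly prescribed patients. Returns `NA` with a
#' warning when either optimal-treatment class is absent.
#'
#' @param prescriptions character vector of `"A"`/`"B"`.
#' @param hidden matching `responsiveness_records` rows.
#' @return real in `[0, 1]`, or `NA`.
#' @export
balanced_accuracy <- function(prescriptions, hidden) {
  stopifnot(length(prescriptions) == nrow(hidden))
  sel_a <- hidden$s == 1
  sel_b <- hidden$s == -1
  if (!any(sel_a) || !any(sel_b)) {
    warning("an optimal-treatment class is absent; balanced accuracy undefined")
    return(NA_real_)
  }
  (mean(prescriptions[sel_a] == "A") + mean(prescriptions[sel_b] == "B")) / 2
}

#' Precision in estimation of heterogeneous effects (PEHE)
#'
#' Root mean squared difference between estimated and true individual
#' treatment effects; dual responders (`tau = 0`) are included.
#'
#' @param tau_hat estimated effects.
#' @param tau true effects.
#' @return nonnegative real.
#' @export
pehe <- function(tau_hat, tau) {
  stopifnot(length(tau_hat) == length(tau))
  if (length(tau) == 0) stop("PEHE undefined on an empty validation set")
  sqrt(mean((tau_hat - tau)^2))
}

#' Assemble the per-patient inputs a condition runner needs
#'
#' Computes, once per (cohort, pair, representation-kind) cell: the hidden
#' responsiveness records, the designating binary masks, the volumes fed to
#' embedders (binary lesions, or probabilistic disconnectomes), and the
#' lesion-centroid coordinate along the pair's confounding axis.
#'
#' @param cohort a `lesion_cohort`.
#' @param pair a `subnetwork_pair`.
#' @param world the `brain_world` (for mask and atlases).
#' @param rep_kind `"lesion"` or `"disconnectome"`.
#' @param tracts a `tract_set` (disconnectome only).
#' @param overlap_threshold responsiveness threshold (default 0.05).
#' @return an object of class `trial_input`.
#' @export
prepare_trial_input <- function(cohort, pair, world,
                                rep_kind = c("lesion", "disconnectome"),
                                tracts = NULL, overlap_threshold = 0.05) {
  rep_kind <- match.arg(rep_kind)
  records <- build_cohort(cohort, pair, rep_kind, tracts,
                          overlap_threshold = overlap_threshold)
  keep <- records$patient_id
  ax <- confounding_axis(pair)$axis
  vols <- list(); masks <- list(); coord <- numeric(0)
  for (p in cohort$patients) {
    if (!(p$patient_id %in% keep)) next
    if (rep_kind == "lesion") {
      vol <- p$lesion
      mask <- p$lesion
    } else {
      vol <- compute_disconnectome(p$lesion, tracts)
      mask <- binarize_disconnectome(vol)
    }
    vols[[p$patient_id]] <- vol
    masks[[p$patient_id]] <- mask
    coord[p$patient_id] <- centroid(mask)[ax]
  }
  structure(list(records = records, volumes = vols, masks = masks,
                 coord = coord, axis = ax,
                 gm_mask = world$gm_mask,
                 atlases = list(two = vascular_atlas(world, "two"),
                                coarse = vascular_atlas(world, "coarse"),
                                fine = vascular_atlas(world, "fine")),
                 rep_kind = rep_kind),
            class = "trial_input")
}

#' A single virtual-trial condition specification
#'
#' @param TE,RE treatment and recovery effects in `[0, 1]`.
#' @param policy list: `kind` (`"randomized"`, `"observable"`,
#'   `"unobservable"`) and `b` (confounding strength; ignored for
#'   randomized).
#' @param representation list: `type` (`"embedding"`, `"baseline"`,
#'   `"oracle"`); for embeddings `method` (`"pca"`, `"nmf"`, `"ae"`,
#'   `"vae"`) and `d`; for baselines `atlas` (`"two"` or `"fine"`).
#' @param learner list: `kind` (`"S"`/`"T"`) and `algorithm` (see
#'   [base_learner()]).
#' @return a `trial_condition` list.
#' @export
trial_condition <- function(TE, RE,
                            policy = list(kind = "randomized", b = 0),
                            representation = list(type = "embedding",
                                                  method = "pca", d = 10),
                            learner = list(kind = "T",
                                           algorithm = "extremely_randomized_trees")) {
  structure(list(TE = TE, RE = RE, policy = policy,
                 representation = representation, learner = learner),
            class = "trial_condition")
}

condition_key <- function(cond) {
  paste(cond$TE, cond$RE, cond$policy$kind, cond$policy$b %||% 0,
        cond$representation$type, cond$representation$method %||% "",
        cond$representation$d %||% "", cond$representation$atlas %||% "",
        cond$learner$kind, cond$learner$algorithm, sep = "|")
}

#' Run one virtual-trial condition under cross-validation
#'
#' Per fold: fit the representation on training-fold volumes only (atlas
#' baselines and oracle features involve no fitting), allocate treatments
#' (the observable policy's training-median is computed on the training
#' fold), sample outcomes, check fittability, fit the meta-learner on the
#' training fold, and score prescriptions and CATE estimates on the
#' validation fold. Degenerate folds are marked and carry no metrics.
#'
#' @param input a `trial_input`.
#' @param condition a `trial_condition`.
#' @param folds named fold assignment from [make_folds()].
#' @param master_seed integer; per-fold seeds are derived from it.
#' @param tau_scale `"effect"` (default) or `"sign"`.
#' @return data.frame with one row per fold: `fold`, `n_val`, `degenerate`,
#'   `balanced_accuracy`, `pehe`.
#' @export
run_condition <- function(input, condition, folds, master_seed = 1,
                          tau_scale = c("effect", "sign")) {
  tau_scale <- match.arg(tau_scale)
  rec <- input$records
  noise <- noise_config(condition$TE, condition$RE)
  tau <- if (tau_scale == "effect") rec$s * (noise$TE - noise$RE) else rec$s
  fold_of <- folds[rec$patient_id]
  if (any(is.na(fold_of))) stop("fold assignment missing for some patients")
  ids <- rec$patient_id
  ckey <- condition_key(condition)
  k <- max(folds)
  out <- vector("list", k)
  for (fk in seq_len(k)) {
    val <- which(fold_of == fk)
    train <- which(fold_of != fk)
    if (length(val) == 0 || length(train) == 0) {
      out[[fk]] <- data.frame(fold = fk, n_val = length(val),
                              degenerate = TRUE,
                              balanced_accuracy = NA_real_, pehe = NA_real_)
      next
    }
    X <- condition_features(input, condition, ids, train, fk, master_seed)
    alloc_seed <- derive_seed(master_seed, paste("alloc", ckey, fk))
    w <- switch(condition$policy$kind,
                randomized = allocate_observable(
                  input$coord[ids], b_obs = 0, seed = alloc_seed,
                  patient_ids = ids)$w,
                observable = allocate_observable(
                  input$coord[ids], b_obs = condition$policy$b,
                  train_median = stats::median(input$coord[ids[train]]),
                  seed = alloc_seed, patient_ids = ids)$w,
                unobservable = allocate_unobservable(
                  rec, condition$policy$b, seed = alloc_seed),
                stop("unknown policy kind: ", condition$policy$kind))
    y <- sample_outcomes(rec, w, noise,
                         seed = derive_seed(master_seed,
                                            paste("y", ckey, fk)))
    if (!check_fittable(w[train], y[train], condition$learner$kind)) {
      out[[fk]] <- data.frame(fold = fk, n_val = length(val),
                              degenerate = TRUE,
                              balanced_accuracy = NA_real_, pehe = NA_real_)
      next
    }
    base <- base_learner(condition$learner$algorithm,
                         seed = derive_seed(master_seed,
                                            paste("base", ckey, fk)))
    model <- if (condition$learner$kind == "S") {
      fit_s_learner(X[train, , drop = FALSE], w[train], y[train], base)
    } else {
      fit_t_learner(X[train, , drop = FALSE], w[train], y[train], base)
    }
    pres <- prescribe(model, X[val, , drop = FALSE])
    est <- estimate_cate(model, X[val, , drop = FALSE])
    ba <- suppressWarnings(balanced_accuracy(pres, rec[val, , drop = FALSE]))
    out[[fk]] <- data.frame(fold = fk, n_val = length(val),
                            degenerate = FALSE,
                            balanced_accuracy = ba,
                            pehe = pehe(est$tau_hat, tau[val]))
  }
  do.call(rbind, out)
}

# fold-hygienic feature construction: embedders see training volumes only
condition_features <- function(input, condition, ids, train, fold, master_seed) {
  rp <- condition$representation
  if (rp$type == "oracle") {
    X <- cbind(r_A = input$records$r_A, r_B = input$records$r_B)
    return(X)
  }
  if (rp$type == "baseline") {
    atlas <- input$atlases[[rp$atlas %||% "two"]]
    X <- t(vapply(ids, function(pid) {
      baseline_phenotype(input$masks[[pid]], atlas)$x
    }, numeric(length(setdiff(unique(as.vector(atlas)), 0L)))))
    return(X)
  }
  emb <- fit_embedder(input$volumes[ids[train]], method = rp$method,
                      d = rp$d,
                      seed = derive_seed(master_seed,
                                         paste("emb", rp$method, rp$d, fold)),
                      gm_mask = input$gm_mask)
  t(vapply(ids, function(pid) embed(emb, input$volumes[[pid]]),
           numeric(rp$d)))
}

#' Run a grid of virtual-trial conditions
#'
#' Crosses every supplied `trial_input` (one per network x criterion x
#' representation-kind cell) with the noise levels, allocation policies,
#' and representation-learner configurations, running [run_condition()]
#' for each cell.
#'
#' @param inputs named list of `trial_input` objects.
#' @param TE_levels,RE_levels numeric vectors.
#' @param policies list of policy lists.
#' @param configs list of `list(representation = ..., learner = ...)` pairs.
#' @param k folds (default 10).
#' @param master_seed integer.
#' @return list with `results` (tidy data.frame, one row per condition x
#'   config x fold) and `accounting` (conditions, configs, folds,
#'   simulations).
#' @export
run_grid <- function(inputs, TE_levels, RE_levels, policies, configs,
                     k = 10, master_seed = 1) {
  n_conditions <- length(inputs) * length(TE_levels) * length(RE_levels) *
    length(policies)
  accounting <- list(conditions = n_conditions, configs = length(configs),
                     folds = k,
                     simulations = n_conditions * length(configs) * k)
  rows <- list()
  for (nm in names(inputs)) {
    input <- inputs[[nm]]
    folds <- make_folds(input$records$patient_id, k = k,
                        seed = derive_seed(master_seed, paste("folds", nm)))
    for (TE in TE_levels) for (RE in RE_levels) {
      for (pi_ in seq_along(policies)) for (ci in seq_along(configs)) {
        cond <- trial_condition(TE, RE, policy = policies[[pi_]],
                                representation = configs[[ci]]$representation,
                                learner = configs[[ci]]$learner)
        res <- run_condition(input, cond, folds, master_seed)
        res$input <- nm; res$TE <- TE; res$RE <- RE
        res$policy <- policies[[pi_]]$kind
        res$b <- policies[[pi_]]$b %||% 0
        res$representation <- paste0(cond$representation$type, ":",
                                     cond$representation$method %||%
                                       cond$representation$atlas %||% "")
        res$d <- cond$representation$d %||% NA
        res$learner <- paste0(cond$learner$kind, ":", cond$learner$algorithm)
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  list(results = if (length(rows)) do.call(rbind, rows) else
    data.frame(), accounting = accounting)
}

#' Grid accounting from level counts
#'
#' `conditions = networks x criteria x representation kinds x TE x RE x
#' policies`; `configs = representations x learners`;
#' `simulations = conditions x configs x folds`.
#'
#' @param n_networks,n_criteria,n_rep_kinds,n_TE,n_RE,n_policies level counts.
#' @param n_representations,n_learners configuration counts.
#' @param k folds.
#' @return list with `conditions`, `configs`, `folds`, `simulations`.
#' @export
grid_accounting <- function(n_networks, n_criteria, n_rep_kinds, n_TE, n_RE,
                            n_policies, n_representations, n_learners,
                            k = 10) {
  conditions <- n_networks * n_criteria * n_rep_kinds * n_TE * n_RE *
    n_policies
  configs <- n_representations * n_learners
  list(conditions = conditions, configs = configs, folds = k,
       simulations = conditions * configs * k)
}

#' Per-trial representation count
#'
#' @param n_baselines atlas baselines (default 2).
#' @param n_dims embedding dimensionalities (default the 11-value ladder
#'   2, 5, 10, ..., 50).
#' @param n_methods embedding methods (default 4: PCA, NMF, AE, VAE).
#' @return integer count.
#' @export
representation_count <- function(n_baselines = 2, n_dims = 11, n_methods = 4) {
  n_baselines + n_dims * n_methods
}

#' Study-scale accounting configuration
#'
#' The full-scale experiment enumerates 16 functional networks, 2
#' responsiveness criteria (receptome/transcriptome), 2 lesion
#' representation kinds (mask/disconnectome), and a noise-by-allocation
#' grid of 352 level combinations, evaluated over 46 representations x 10
#' meta-learner/classifier pairs under 10-fold cross-validation.
#'
#' @return the [grid_accounting()] list for the full-scale study.
#' @export
study_scale_accounting <- function() {
  grid_accounting(n_networks = 16, n_criteria = 2, n_rep_kinds = 2,
                  n_TE = 4, n_RE = 4, n_policies = 22,
                  n_representations = representation_count(),
                  n_learners = 10, k = 10)
}

#' Two-group comparison: t-test and Cohen's d
#'
#' Two-sided independent-samples Student (pooled-variance) t-test and
#' pooled-SD Cohen's d. Two zero-variance groups with equal means return
#' `t = 0, p = 1, d = 0`.
#'
#' @param metric_a,metric_b numeric vectors (each length >= 2).
#' @param var_equal pooled variance (default TRUE); set FALSE for Welch.
#' @return list with `t`, `p`, `cohens_d`, `n_a`, `n_b`.
#' @export
compare_groups <- function(metric_a, metric_b, var_equal = TRUE) {
  stopifnot(length(metric_a) >= 2, length(metric_b) >= 2)
  na <- length(metric_a); nb <- length(metric_b)
  sp2 <- ((na - 1) * stats::var(metric_a) + (nb - 1) * stats::var(metric_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    if (mean(metric_a) == mean(metric_b)) {
      return(list(t = 0, p = 1, cohens_d = 0, n_a = na, n_b = nb))
    }
    return(list(t = sign(mean(metric_a) - mean(metric_b)) * Inf, p = 0,
                cohens_d = sign(mean(metric_a) - mean(metric_b)) * Inf,
                n_a = na, n_b = nb))
  }
  tt <- stats::t.test(metric_a, metric_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       cohens_d = (mean(metric_a) - mean(metric_b)) / sqrt(sp2),
       n_a = na, n_b = nb)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Flags true for all hypotheses with p-value at or below the largest
#' `p_(i) <= (i/m) q` threshold.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return logical vector aligned with `p_values`.
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0) return(logical(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0) return(rep(FALSE, m))
  p_values <= ps[max(ok)]
}
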