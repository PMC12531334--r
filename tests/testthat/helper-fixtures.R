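# Shared fixtures, built lazily and memoized for the whole test run.
# Every fixture is a pure function of fixed seeds: tests may assert exact
# values against them.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_env[[name]])) assign(name, builder(), envir = .fx_env)
  .fx_env[[name]]
}

# small world: 16^3 grid, 4 planted networks
fx_world <- function() fx("world", function() {
  generate_world(grid_spec(c(16, 16, 16)), n_networks = 4, seed = 1)
})

fx_receptors <- function() fx("receptors", function() {
  generate_receptors(fx_world(), n_receptors = 4, smoothness_vox = 2, seed = 3)
})

fx_pair <- function() fx("pair", function() {
  subdivide_receptome(network_mask(fx_world(), 2), fx_receptors(),
                      network_id = 2)
})

fx_lesions <- function() fx("lesions", function() {
  generate_lesions(fx_world(), n_patients = 150,
                   size_range_vox = c(15, 60), seed = 5)
})

fx_input <- function() fx("input", function() {
  prepare_trial_input(fx_lesions(), fx_pair(), fx_world(), "lesion")
})

fx_folds <- function(k = 10) {
  fx(paste0("folds", k), function() {
    make_folds(fx_input()$records$patient_id, k = k, seed = 2)
  })
}

fx_tracts <- function() fx("tracts", function() {
  generate_tracts(fx_world(), n_subjects = 4, bundles_per_subject = 6,
                  seed = 7)
})

# discrete, mildly unbalanced, fully separable fixture for learner tests:
# x = (r_A, r_B) with all three responder classes present
fx_discrete <- function() fx("discrete", function() {
  s <- rep(c(1L, -1L, 0L), times = c(25, 20, 15))
  rec <- data.frame(patient_id = sprintf("q%03d", seq_along(s)),
                    r_A = as.integer(s >= 0), r_B = as.integer(s <= 0),
                    s = s,
                    w_star = ifelse(s > 0, "A", ifelse(s < 0, "B", "either")),
                    stringsAsFactors = FALSE)
  rec$tau <- rec$s
  class(rec) <- c("responsiveness_records", "data.frame")
  rec
})

fx_discrete_xy <- function(seed = 11) {
  rec <- fx_discrete()
  X <- cbind(r_A = rec$r_A, r_B = rec$r_B)
  noise <- noise_config(1, 0)
  w <- allocate_observable(seq_len(nrow(rec)), b_obs = 0, seed = seed,
                           patient_ids = rec$patient_id)$w
  y <- sample_outcomes(rec, w, noise, seed = seed)
  list(rec = rec, X = X, w = w, y = y)
}

# synthetic responder records of arbitrary size (no imaging involved)
fx_records <- function(n_pos, n_neg, n_dual = 0) {
  s <- rep(c(1L, -1L, 0L), times = c(n_pos, n_neg, n_dual))
  rec <- data.frame(patient_id = sprintf("r%05d", seq_along(s)),
                    r_A = as.integer(s >= 0), r_B = as.integer(s <= 0),
                    s = s,
                    w_star = ifelse(s > 0, "A", ifelse(s < 0, "B", "either")),
                    stringsAsFactors = FALSE)
  rec$tau <- rec$s
  class(rec) <- c("responsiveness_records", "data.frame")
  rec
}
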