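test_that("observable allocation has the specified rho endpoints", {
  # b = 0, N = 5: randomized limit
  a0 <- allocate_observable(c(3, 1, 4, 1, 5), b_obs = 0, seed = 1)
  expect_equal(a0$rho, rep(0.5, 5))
  # b = 0.5, N = 3: linspace endpoints (0, 0.5, 1) in rank order
  a5 <- allocate_observable(c(10, 30, 20), b_obs = 0.5, seed = 1)
  expect_equal(a5$rho, c(0, 1, 0.5))  # input order; ranks are 1, 3, 2
  # b = 1: fully deterministic by train-median side, identical over seeds
  co <- c(9, 2, 7, 4, 6, 1)
  a1 <- allocate_observable(co, b_obs = 1, seed = 1)
  a1b <- allocate_observable(co, b_obs = 1, seed = 999)
  expect_identical(a1$w, a1b$w)
  expect_identical(a1$w, ifelse(co >= median(co), "B", "A"))
  expect_true(all(a1$rho %in% c(0, 1)))
  expect_error(allocate_observable(co, b_obs = 1.2), "\\[0, 1\\]")
})

test_that("the deterministic-extremes regime follows the rank-midpoint rule", {
  co <- c(1, 2, 3, 4)  # already ranked
  # b = 0.75: f = 0.25; midpoints (.125, .375, .625, .875) -> ranks 1 and 4
  a <- allocate_observable(co, b_obs = 0.75, train_median = 2.5, seed = 3)
  expect_identical(a$w[1], "A")   # below the median, deterministic
  expect_identical(a$w[4], "B")   # above the median, deterministic
  expect_equal(a$rho[2:3], c(0, 1))  # interior rho spans [0, 1]
  # continuity at b = 0.5: both regimes give rho spanning [0, 1]
  r_low <- allocate_observable(co, b_obs = 0.5, seed = 3)$rho
  r_high <- allocate_observable(co, b_obs = 0.5 + 1e-9, seed = 3)$rho
  expect_equal(r_low, r_high, tolerance = 1e-6)
})

test_that("coordinate ties are broken stably by patient id", {
  co <- c(5, 5, 5)
  a <- allocate_observable(co, b_obs = 0.5, seed = 1,
                           patient_ids = c("a", "b", "c"))
  expect_equal(a$rho, c(0, 0.5, 1))
  a2 <- allocate_observable(co, b_obs = 0.5, seed = 1,
                            patient_ids = c("c", "b", "a"))
  expect_equal(a2$rho, c(1, 0.5, 0))
})

test_that("randomized limit is balanced over repeated seeds", {
  co <- seq_len(50)
  n_b <- vapply(1:200, function(s) {
    sum(allocate_observable(co, b_obs = 0, seed = s)$w == "B")
  }, numeric(1))
  # 99% binomial band around 25 of 50, averaged over 200 reps
  p_hat <- mean(n_b) / 50
  half <- 2.576 * 0.5 / sqrt(50 * 200)
  expect_lt(abs(p_hat - 0.5), half + 1e-12)
})

test_that("rank-to-arm association increases with b_obs", {
  co <- seq_len(40)
  assoc <- vapply(c(0.1, 0.25, 0.4), function(b) {
    pb <- rowMeans(vapply(1:150, function(s) {
      as.numeric(allocate_observable(co, b_obs = b, seed = s)$w == "B")
    }, numeric(40)))
    cor(seq_len(40), pb, method = "spearman")
  }, numeric(1))
  expect_true(all(diff(assoc) > 0))
  expect_true(all(assoc > 0))
})

test_that("unobservable allocation honours its limits and independence", {
  rec_a <- fx_records(30, 0)
  expect_true(all(allocate_unobservable(rec_a, 1, seed = 1) == "A"))
  expect_true(all(allocate_unobservable(rec_a, 0, seed = 1) == "B"))
  expect_error(allocate_unobservable(rec_a, 2), "\\[0, 1\\]")
  # b = 0.5: allocation independent of the hidden optimum at N = 10000
  rec <- fx_records(5000, 5000)
  w <- allocate_unobservable(rec, 0.5, seed = 7)
  expect_lt(abs(cor(as.numeric(w == "A"), as.numeric(rec$w_star == "A"))),
            0.03)
  # dual responders get a fair coin
  rec_d <- fx_records(0, 0, 4000)
  wd <- allocate_unobservable(rec_d, 1, seed = 7)
  expect_lt(abs(mean(wd == "A") - 0.5), 0.03)
})

test_that("outcome sampling is exact at the noiseless endpoint", {
  rec <- fx_records(10, 10, 5)
  w <- rep(c("A", "B"), length.out = nrow(rec))
  y <- sample_outcomes(rec, w, noise_config(1, 0), seed = 1)
  suitable <- rec$w_star == "either" | rec$w_star == w
  expect_identical(y, as.integer(suitable))
  # TE = RE = p: empirical P(y = 1) matches p
  ys <- unlist(lapply(1:30, function(s) {
    sample_outcomes(rec, w, noise_config(0.3, 0.3), seed = s)
  }))
  expect_lt(abs(mean(ys) - 0.3), 2.576 * sqrt(0.3 * 0.7 / length(ys)))
  # deterministic under the seed
  expect_identical(sample_outcomes(rec, w, noise_config(0.6, 0.2), seed = 4),
                   sample_outcomes(rec, w, noise_config(0.6, 0.2), seed = 4))
})

test_that("fittability reflects arm and outcome degeneracy", {
  expect_true(check_fittable(c("A", "A", "B", "B"), c(0, 1, 0, 1), "T"))
  expect_false(check_fittable(c("A", "A", "A", "A"), c(0, 1, 0, 1), "T"))
  expect_false(check_fittable(c("A", "A", "B", "B"), c(1, 1, 1, 1), "S"))
  # single-class within one arm: degenerate for T, fine for S
  expect_false(check_fittable(c("A", "A", "B", "B"), c(0, 1, 1, 1), "T"))
  expect_true(check_fittable(c("A", "A", "B", "B"), c(0, 1, 1, 1), "S"))
})

test_that("run_condition marks degenerate conditions instead of failing", {
  input <- fx_input()
  folds <- fx_folds(5)
  cond <- trial_condition(TE = 0, RE = 0,
                          policy = list(kind = "randomized", b = 0),
                          representation = list(type = "oracle"),
                          learner = list(kind = "T",
                                         algorithm = "lookup_table"))
  res <- run_condition(input, cond, folds, master_seed = 1)
  expect_true(all(res$degenerate))       # all y = 0: nothing to fit
  expect_true(all(is.na(res$balanced_accuracy)))
  expect_true(all(is.na(res$pehe)))
})

test_that("run_condition is reproducible and honours the policy kinds", {
  input <- fx_input()
  folds <- fx_folds(5)
  for (pol in list(list(kind = "randomized", b = 0),
                   list(kind = "observable", b = 0.6),
                   list(kind = "unobservable", b = 0.9))) {
    cond <- trial_condition(TE = 0.9, RE = 0.1, policy = pol,
                            representation = list(type = "oracle"),
                            learner = list(kind = "S",
                                           algorithm = "lookup_table"))
    r1 <- run_condition(input, cond, folds, master_seed = 3)
    r2 <- run_condition(input, cond, folds, master_seed = 3)
    expect_identical(r1, r2)
    expect_identical(nrow(r1), 5L)
    expect_true(all(r1$pehe[!r1$degenerate] >= 0))
    ok <- !is.na(r1$balanced_accuracy)
    expect_true(all(r1$balanced_accuracy[ok] >= 0 &
                      r1$balanced_accuracy[ok] <= 1))
  }
})

test_that("run_grid enumerates the product and reports accounting", {
  input <- fx_input()
  configs <- list(
    list(representation = list(type = "oracle"),
         learner = list(kind = "T", algorithm = "lookup_table")),
    list(representation = list(type = "baseline", atlas = "two"),
         learner = list(kind = "S", algorithm = "lookup_table")))
  out <- run_grid(list(net2 = input), TE_levels = c(0.9, 0.7),
                  RE_levels = 0.1,
                  policies = list(list(kind = "randomized", b = 0)),
                  configs = configs, k = 5, master_seed = 1)
  expect_equal(out$accounting$conditions, 2)
  expect_equal(out$accounting$simulations, 20)
  expect_identical(nrow(out$results), 20L)
  expect_setequal(unique(out$results$TE), c(0.9, 0.7))
  # empty grid: empty table, no error
  empty <- run_grid(list(), TE_levels = 0.9, RE_levels = 0.1,
                    policies = list(list(kind = "randomized", b = 0)),
                    configs = configs, k = 5)
  expect_identical(nrow(empty$results), 0L)
  expect_identical(empty$accounting$conditions, 0L)
})
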