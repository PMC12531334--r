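#' Base learner specification
#'
#' The roster of probabilistic outcome classifiers usable inside the S-/T-
#' meta-learners. All stochastic learners are seeded. `"lookup_table"` is a
#' saturated conditional-frequency estimator over discrete feature rows,
#' used as an exact oracle in tests.
#'
#' @param algorithm one of `"extremely_randomized_trees"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`, `"logistic_regression"`,
#'   `"gaussian_process"`, `"lookup_table"`.
#' @param seed integer seed threaded to every stochastic fit.
#' @param settings named list of overrides merged over the defaults.
#' @return an object of class `base_learner_spec`.
#' @export
base_learner <- function(algorithm = c("extremely_randomized_trees",
                                       "random_forest",
                                       "gradient_boosted_trees",
                                       "logistic_regression",
                                       "gaussian_process",
                                       "lookup_table"),
                         seed = 1, settings = list()) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, seed = seed, settings = settings),
            class = "base_learner_spec")
}

as_feature_df <- function(X) {
  X <- as.matrix(X)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df
}

# fit one probabilistic classifier; y is 0/1
fit_base <- function(spec, X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 2) stop("cannot fit a classifier to fewer than 2 rows")
  if (length(unique(y)) < 2) {
    stop("degenerate data: outcome is single-class")
  }
  s <- spec$settings
  alg <- spec$algorithm
  model <- switch(
    alg,
    extremely_randomized_trees = {
      df <- as_feature_df(X); df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     splitrule = "extratrees",
                     num.random.splits = s$num.random.splits %||% 1,
                     replace = FALSE, sample.fraction = 1,
                     mtry = s$mtry %||% ncol(X),
                     min.node.size = s$min.node.size %||% 1,
                     num.trees = s$num.trees %||% 500,
                     seed = spec$seed, num.threads = 1)
    },
    random_forest = {
      df <- as_feature_df(X); df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     mtry = s$mtry %||% ncol(X),
                     min.node.size = s$min.node.size %||% 1,
                     num.trees = s$num.trees %||% 500,
                     seed = spec$seed, num.threads = 1)
    },
    gradient_boosted_trees = {
      dm <- xgboost::xgb.DMatrix(X, label = y)
      with_seed(spec$seed,
                xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                 nthread = 1,
                                                 max_depth = s$max_depth %||% 6,
                                                 eta = s$eta %||% 0.3),
                                   data = dm,
                                   nrounds = s$nrounds %||% 100,
                                   verbose = 0))
    },
    logistic_regression = {
      df <- as_feature_df(X); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    gaussian_process = {
      max_n <- s$max_n %||% 2000
      idx <- seq_len(nrow(X))
      if (length(idx) > max_n) { # documented seeded subsample rule
        idx <- with_seed(derive_seed(spec$seed, "gp/subsample"),
                         sort(sample(idx, max_n)))
      }
      with_seed(spec$seed, {
        fit <- kernlab::gausspr(x = X[idx, , drop = FALSE],
                                y = factor(y[idx], levels = c(0, 1)))
        fit
      })
    },
    lookup_table = {
      key <- apply(X, 1, paste, collapse = "\r")
      tab <- tapply(y, key, mean)
      list(table = tab, fallback = mean(y))
    })
  structure(list(algorithm = alg, model = model, p = ncol(X)),
            class = "fitted_base")
}

# probability of the favourable outcome for each row of X
predict_base <- function(fit, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == fit$p)
  switch(
    fit$algorithm,
    extremely_randomized_trees = ,
    random_forest = {
      pr <- stats::predict(fit$model, data = as_feature_df(X),
                           num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    gradient_boosted_trees = {
      as.numeric(stats::predict(fit$model, xgboost::xgb.DMatrix(X)))
    },
    logistic_regression = {
      as.numeric(stats::predict(fit$model, newdata = as_feature_df(X),
                                type = "response"))
    },
    gaussian_process = {
      pr <- kernlab::predict(fit$model, X, type = "probabilities")
      as.numeric(pr[, which(colnames(pr) == "1")])
    },
    lookup_table = {
      key <- apply(X, 1, paste, collapse = "\r")
      out <- fit$model$table[key]
      out[is.na(out)] <- fit$model$fallback
      as.numeric(out)
    })
}

#' Fit a one-model (S-learner) conditional-outcome model
#'
#' A single classifier is fitted to features `[x, delta]` where `delta` is
#' the Kronecker treatment indicator (1 for arm A), targeting the observed
#' outcome.
#'
#' @param X phenotype matrix (n x d).
#' @param w allocation vector of `"A"`/`"B"`.
#' @param y 0/1 outcomes.
#' @param base a `base_learner_spec`.
#' @return an object of class `meta_learner` with `kind = "S"`.
#' @export
fit_s_learner <- function(X, w, y, base) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(w), length(w) == length(y))
  Xs <- cbind(X, .treatA = as.numeric(w == "A"))
  structure(list(kind = "S", components = list(all = fit_base(base, Xs, y)),
                 base = base, d = ncol(X)),
            class = "meta_learner")
}

#' Fit a two-model (T-learner) conditional-outcome model
#'
#' One classifier per arm, each fitted to that arm's rows only. Both arms
#' must be nonempty with both outcome classes; no rebalancing is applied.
#'
#' @inheritParams fit_s_learner
#' @return an object of class `meta_learner` with `kind = "T"`.
#' @export
fit_t_learner <- function(X, w, y, base) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(w), length(w) == length(y))
  comps <- lapply(c(A = "A", B = "B"), function(arm) {
    sel <- w == arm
    if (!any(sel)) stop("degenerate data: arm ", arm, " is empty")
    fit_base(base, X[sel, , drop = FALSE], y[sel])
  })
  structure(list(kind = "T", components = comps, base = base, d = ncol(X)),
            class = "meta_learner")
}

#' @export
print.meta_learner <- function(x, ...) {
  cat("<meta_learner>", x$kind, "-learner |", x$base$algorithm,
      "| d =", x$d, "\n")
  invisible(x)
}

#' Predicted outcome probability under a counterfactual treatment
#'
#' @param model a fitted `meta_learner`.
#' @param X phenotype matrix (rows to predict).
#' @param w `"A"` or `"B"` (applied to all rows).
#' @return probabilities in `[0, 1]`.
#' @export
outcome_prob <- function(model, X, w) {
  stopifnot(inherits(model, "meta_learner"), w %in% c("A", "B"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("phenotype dimensionality mismatch")
  if (model$kind == "S") {
    predict_base(model$components$all,
                 cbind(X, .treatA = as.numeric(w == "A")))
  } else {
    predict_base(model$components[[w]], X)
  }
}

#' Estimate the conditional average treatment effect
#'
#' `tau_hat(x) = P(Y = 1 | W = A, x) - P(Y = 1 | W = B, x)`, bounded in
#' `[-1, 1]`.
#'
#' @param model a fitted `meta_learner`.
#' @param X phenotype matrix.
#' @return data.frame with `p_A`, `p_B`, `tau_hat`.
#' @export
estimate_cate <- function(model, X) {
  p_A <- outcome_prob(model, X, "A")
  p_B <- outcome_prob(model, X, "B")
  data.frame(p_A = p_A, p_B = p_B, tau_hat = p_A - p_B)
}

#' Prescribe the treatment with the greater predicted outcome probability
#'
#' Exact ties go to A (deterministic, documented).
#'
#' @param model a fitted `meta_learner`.
#' @param X phenotype matrix.
#' @return character vector of `"A"`/`"B"`.
#' @export
prescribe <- function(model, X) {
  ce <- estimate_cate(model, X)
  ifelse(ce$p_A >= ce$p_B, "A", "B")
}
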