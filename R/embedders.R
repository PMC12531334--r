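#' Fit a lesion-representation embedder
#'
#' Learns a `d`-dimensional phenotype representation from training-fold
#' volumes only (fold hygiene is the caller's contract; [run_condition()]
#' enforces it). Volumes are vectorized over the grey-matter mask, dropping
#' constant background dimensions.
#'
#' Methods: `"pca"` ([stats::prcomp()], centred), `"nmf"` (multiplicative
#' Lee–Seung updates, seeded random initialization; inputs must be
#' nonnegative), `"ae"` and `"vae"` (small fully connected autoencoders
#' trained with Adam; batch 10, 16–32 epochs with early stopping after 4
#' non-improving epochs).
#'
#' @param train_volumes list of volumes (identical shape) or an n x V matrix
#'   already masked.
#' @param method `"pca"`, `"nmf"`, `"ae"`, or `"vae"`.
#' @param d embedding dimensionality; must not exceed the number of
#'   training volumes.
#' @param seed integer seed (threaded to every stochastic step).
#' @param gm_mask binary volume used to vectorize (required when
#'   `train_volumes` is a list of volumes).
#' @param ... method options: `nmf_iter` (default 200), `hidden` (default
#'   64), `epochs_min`/`epochs_max` (16/32), `batch_size` (10),
#'   `learning_rate` (1e-3), `patience` (4), `beta` (VAE KL weight, 1).
#' @return an object of class `embedder`.
#' @export
fit_embedder <- function(train_volumes, method = c("pca", "nmf", "ae", "vae"),
                         d, seed = 1, gm_mask = NULL, ...) {
  method <- match.arg(method)
  opts <- list(...)
  X <- as_masked_matrix(train_volumes, gm_mask)
  n <- nrow(X); V <- ncol(X)
  if (d > n) stop("d = ", d, " exceeds the ", n, " training volumes")
  if (method == "nmf" && any(X < 0)) stop("NMF requires nonnegative inputs")
  fitted <- switch(
    method,
    pca = {
      p <- stats::prcomp(X, center = TRUE, rank. = min(d, n - 1, V))
      # pad in the degenerate d >= rank case so x always has length d
      rot <- p$rotation
      if (ncol(rot) < d) {
        rot <- cbind(rot, matrix(0, V, d - ncol(rot)))
      }
      list(rotation = rot, center = p$center, sdev = p$sdev)
    },
    nmf = with_seed(derive_seed(seed, "nmf"), {
      nmf_fit(X, d, iter = opts$nmf_iter %||% 200)
    }),
    ae = with_seed(derive_seed(seed, "ae"), {
      ae_fit(X, d, variational = FALSE, opts = opts)
    }),
    vae = with_seed(derive_seed(seed, "vae"), {
      ae_fit(X, d, variational = TRUE, opts = opts)
    }))
  structure(list(method = method, d = d, fitted_params = fitted,
                 fit_seed = seed, gm_mask = gm_mask, n_train = n),
            class = "embedder")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_masked_matrix <- function(volumes, gm_mask) {
  if (is.matrix(volumes)) return(volumes)
  stopifnot(is.list(volumes), length(volumes) >= 1)
  if (is.null(gm_mask)) stop("gm_mask is required to vectorize volumes")
  idx <- which(gm_mask != 0)
  t(vapply(volumes, function(v) {
    stopifnot_same_shape(v, gm_mask)
    as.numeric(v[idx])
  }, numeric(length(idx))))
}

#' Embed a volume into its phenotype vector
#'
#' Deterministic: repeated calls give identical results; for the VAE the
#' posterior mean is returned, never a sample.
#'
#' @param embedder a fitted `embedder`.
#' @param volume a volume (or masked numeric vector) on the fitting grid.
#' @return numeric phenotype vector of length `d`.
#' @export
embed <- function(embedder, volume) {
  x <- as_masked_vector(volume, embedder$gm_mask)
  f <- embedder$fitted_params
  switch(embedder$method,
         pca = as.numeric((x - f$center) %*% f$rotation[, seq_len(embedder$d)]),
         nmf = nmf_project(x, f$H),
         ae = ,
         vae = ae_encode(f, x)$mu)
}

as_masked_vector <- function(volume, gm_mask) {
  if (is.null(dim(volume))) return(as.numeric(volume))
  if (is.null(gm_mask)) stop("embedder has no mask; pass a masked vector")
  stopifnot_same_shape(volume, gm_mask)
  as.numeric(volume[gm_mask != 0])
}

#' Reconstruct a volume-space vector from a phenotype
#'
#' Inverse map of [embed()] (approximate for lossy embeddings); used for
#' round-trip diagnostics.
#'
#' @param embedder a fitted `embedder`.
#' @param x phenotype vector of length `d`.
#' @return numeric vector over the grey mask.
#' @export
reconstruct <- function(embedder, x) {
  f <- embedder$fitted_params
  switch(embedder$method,
         pca = as.numeric(f$rotation[, seq_len(embedder$d)] %*% x + f$center),
         nmf = as.numeric(x %*% f$H),
         ae = ,
         vae = ae_decode(f, matrix(x, nrow = 1))[1, ])
}

#' Volume image of one latent component
#'
#' PCA: the loading vector (unit norm). NMF: the basis row (nonnegative).
#' AE/VAE: the decoder image of the unit latent vector.
#'
#' @param embedder a fitted `embedder`.
#' @param component_index 1-based index `<= d`.
#' @return a volume on the fitting grid (or a masked vector without a mask).
#' @export
archetype <- function(embedder, component_index) {
  if (component_index < 1 || component_index > embedder$d) {
    stop("component index out of range")
  }
  f <- embedder$fitted_params
  v <- switch(embedder$method,
              pca = f$rotation[, component_index],
              nmf = f$H[component_index, ],
              ae = ,
              vae = {
                z <- rep(0, embedder$d); z[component_index] <- 1
                ae_decode(f, matrix(z, nrow = 1))[1, ]
              })
  if (is.null(embedder$gm_mask)) return(as.numeric(v))
  out <- array(0, dim(embedder$gm_mask))
  out[embedder$gm_mask != 0] <- v
  out
}

#' Atlas-based baseline phenotype
#'
#' The occluded territory is the atlas label with the greatest Dice overlap
#' with the lesion (exact ties broken by the lowest label id); the phenotype
#' is the corresponding one-hot coding over all atlas labels.
#'
#' @param lesion binary volume.
#' @param atlas integer label volume partitioning the grey matter.
#' @return list with `territory` (label) and `x` (one-hot vector named by
#'   label).
#' @export
baseline_phenotype <- function(lesion, atlas) {
  stopifnot_same_shape(lesion, atlas)
  if (sum(lesion != 0) == 0) stop("empty lesion")
  labs <- sort(setdiff(unique(as.vector(atlas)), 0L))
  dvals <- vapply(labs, function(lb) dice(lesion, atlas == lb), numeric(1))
  if (max(dvals) == 0) stop("lesion lies outside all atlas territories")
  territory <- labs[which.max(dvals)] # which.max: first max = lowest label
  x <- as.numeric(labs == territory)
  names(x) <- paste0("territory", labs)
  list(territory = territory, x = x)
}

# ---- NMF (multiplicative updates) ------------------------------------------

nmf_fit <- function(X, d, iter = 200, eps = 1e-9) {
  n <- nrow(X); V <- ncol(X)
  # random-column-like init: scale of the data, strictly positive
  W <- matrix(stats::runif(n * d, 0, max(X) + eps), n, d)
  H <- matrix(stats::runif(d * V, 0, max(X) + eps), d, V)
  for (it in seq_len(iter)) {
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  list(W = W, H = H)
}

nmf_project <- function(x, H, iter = 100, eps = 1e-9) {
  w <- matrix(1, 1, nrow(H))
  x <- matrix(x, nrow = 1)
  HH <- H %*% t(H)
  xH <- x %*% t(H)
  for (it in seq_len(iter)) {
    w <- w * xH / (w %*% HH + eps)
  }
  as.numeric(w)
}

# ---- small fully connected (V)AE with manual backprop + Adam ---------------

ae_init <- function(V, hidden, d, variational) {
  rn <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / a)), a, b)
  p <- list(W1 = rn(V, hidden), b1 = rep(0, hidden),
            W2 = rn(hidden, d), b2 = rep(0, d),
            W3 = rn(d, hidden), b3 = rep(0, hidden),
            W4 = rn(hidden, V), b4 = rep(0, V))
  if (variational) {
    p$W2l <- rn(hidden, d); p$b2l <- rep(0, d)
  }
  p
}

ae_encode <- function(f, x) {
  X <- matrix(x, nrow = 1)
  A1 <- pmax(sweep(X %*% f$params$W1, 2, f$params$b1, "+"), 0)
  mu <- sweep(A1 %*% f$params$W2, 2, f$params$b2, "+")
  list(mu = as.numeric(mu))
}

ae_decode <- function(f, Z) {
  A3 <- pmax(sweep(Z %*% f$params$W3, 2, f$params$b3, "+"), 0)
  1 / (1 + exp(-sweep(A3 %*% f$params$W4, 2, f$params$b4, "+")))
}

ae_fit <- function(X, d, variational, opts) {
  hidden <- opts$hidden %||% 64
  epochs_min <- opts$epochs_min %||% 16
  epochs_max <- opts$epochs_max %||% 32
  batch_size <- opts$batch_size %||% 10
  lr <- opts$learning_rate %||% 1e-3
  patience <- opts$patience %||% 4
  beta <- opts$beta %||% 1
  n <- nrow(X); V <- ncol(X)
  p <- ae_init(V, hidden, d, variational)
  adam <- lapply(p, function(w) list(m = w * 0, v = w * 0))
  t_step <- 0
  step <- function(g) {
    t_step <<- t_step + 1
    for (nm in names(g)) {
      adam[[nm]]$m <<- 0.9 * adam[[nm]]$m + 0.1 * g[[nm]]
      adam[[nm]]$v <<- 0.999 * adam[[nm]]$v + 0.001 * g[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - 0.9^t_step)
      vhat <- adam[[nm]]$v / (1 - 0.999^t_step)
      p[[nm]] <<- p[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    }
  }
  best <- Inf; flat <- 0
  for (epoch in seq_len(epochs_max)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      Z1 <- sweep(Xb %*% p$W1, 2, p$b1, "+"); A1 <- pmax(Z1, 0)
      M <- sweep(A1 %*% p$W2, 2, p$b2, "+")
      if (variational) {
        LV <- sweep(A1 %*% p$W2l, 2, p$b2l, "+")
        LV <- pmin(pmax(LV, -8), 8)
        EPS <- matrix(stats::rnorm(B * d), B, d)
        Z <- M + EPS * exp(LV / 2)
      } else {
        Z <- M
      }
      Z3 <- sweep(Z %*% p$W3, 2, p$b3, "+"); A3 <- pmax(Z3, 0)
      Z4 <- sweep(A3 %*% p$W4, 2, p$b4, "+")
      Xh <- 1 / (1 + exp(-Z4))
      loss <- mean((Xh - Xb)^2)
      if (variational) {
        loss <- loss + beta * (-0.5 * sum(1 + LV - M^2 - exp(LV))) / (B * V)
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1
      dZ4 <- 2 * (Xh - Xb) / (B * V) * Xh * (1 - Xh)
      g <- list(W4 = t(A3) %*% dZ4, b4 = colSums(dZ4))
      dA3 <- dZ4 %*% t(p$W4); dZ3 <- dA3 * (Z3 > 0)
      g$W3 <- t(Z) %*% dZ3; g$b3 <- colSums(dZ3)
      dZ <- dZ3 %*% t(p$W3)
      if (variational) {
        dM <- dZ + beta * M / (B * V)
        dLV <- dZ * EPS * 0.5 * exp(LV / 2) +
          beta * 0.5 * (exp(LV) - 1) / (B * V)
        g$W2l <- t(A1) %*% dLV; g$b2l <- colSums(dLV)
        dA1 <- dM %*% t(p$W2) + dLV %*% t(p$W2l)
      } else {
        dM <- dZ
        dA1 <- dM %*% t(p$W2)
      }
      g$W2 <- t(A1) %*% dM; g$b2 <- colSums(dM)
      dZ1 <- dA1 * (Z1 > 0)
      g$W1 <- t(Xb) %*% dZ1; g$b1 <- colSums(dZ1)
      step(g)
    }
    ep_loss <- ep_loss / nb
    if (ep_loss < best - 1e-6) { best <- ep_loss; flat <- 0 } else flat <- flat + 1
    if (epoch >= epochs_min && flat >= patience) break
  }
  list(params = p, variational = variational, hidden = hidden, d = d)
}
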