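#' Derive a reproducible child seed from a master seed and a key
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' master seed and a human-readable key (e.g. `"alloc/net3/fold2"`), so any
#' grid cell can be replayed in isolation without replaying the whole run.
#' The hash is a simple 32-bit polynomial rolling hash of the key mixed with
#' the master seed; the result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param key character scalar naming the consumer.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (cc in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + cc) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# ---- volume helpers ---------------------------------------------------------

# coordinates (n x 3, 1-based) of TRUE voxels in a logical/0-1 array
vox_coords <- function(vol) {
  which(vol != 0, arr.ind = TRUE)
}

# build an array of `dims` with value `values` at 1-based coordinates `coords`
vol_from_coords <- function(coords, dims, values = 1) {
  v <- array(0, dim = dims)
  if (NROW(coords) > 0) v[coords] <- values
  v
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("volume shapes differ: (", paste(dim(a), collapse = ","), ") vs (",
         paste(dim(b), collapse = ","), ")", call. = FALSE)
  }
}

# 26-connectivity neighbour offsets (or 6-connectivity)
neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

#' Label connected components of a binary volume
#'
#' Flood fill over the voxel lattice. Used for island cleanup in the
#' parcellation and for the component count in the transcriptome-subdivision
#' objective.
#'
#' @param mask logical/0-1 3D array.
#' @param connectivity 26 (default) or 6.
#' @return integer array of the same shape; 0 outside the mask, components
#'   labelled 1..n in discovery order.
#' @export
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  lab <- array(0L, dims)
  offs <- neighbour_offsets(connectivity)
  idx <- which(mask != 0)
  if (length(idx) == 0L) return(lab)
  nxt <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, dims)
      nb <- sweep(offs, 2L, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
      lin <- lin[mask[lin] != 0 & lab[lin] == 0L]
      if (length(lin) > 0L) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

# Separable 3D Gaussian smoothing with sd `sigma` (in voxels).
# Kernel truncated at 3 sigma; edges handled by zero padding.
gaussian_smooth3d <- function(vol, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  dims <- dim(vol)
  conv_axis <- function(v, axis) {
    out <- array(0, dims)
    for (s in seq_along(k)) {
      off <- s - r - 1L
      src <- seq_len(dims[axis]) - off
      ok <- src >= 1 & src <= dims[axis]
      if (!any(ok)) next
      dst_idx <- which(ok)
      src_idx <- src[ok]
      if (axis == 1) {
        out[dst_idx, , ] <- out[dst_idx, , ] + k[s] * v[src_idx, , ]
      } else if (axis == 2) {
        out[, dst_idx, ] <- out[, dst_idx, ] + k[s] * v[, src_idx, ]
      } else {
        out[, , dst_idx] <- out[, , dst_idx] + k[s] * v[, , src_idx]
      }
    }
    out
  }
  conv_axis(conv_axis(conv_axis(vol, 1), 2), 3)
}

# k nearest donor voxels by Euclidean distance on voxel coordinates;
# returns the majority vote of `donor_labels`, ties to the smallest label.
knn_majority_label <- function(point, donor_coords, donor_labels, k = 5) {
  d2 <- colSums((t(donor_coords) - as.numeric(point))^2)
  nn <- order(d2)[seq_len(min(k, length(d2)))]
  tab <- sort(table(donor_labels[nn]), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1]]
  as.integer(min(as.integer(winners)))
}
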