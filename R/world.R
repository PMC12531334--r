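#' Grid specification shared by all volumes of a run
#'
#' @param dims three positive integers (voxels per axis), each >= 8.
#' @param voxel_size_mm positive voxel edge length in millimetres.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(dims = c(24L, 24L, 24L), voxel_size_mm = 2) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 8L), voxel_size_mm > 0)
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm),
            class = "grid_spec")
}

#' Generate a synthetic brain world
#'
#' Builds the shared substrate for a simulation run: an ellipsoidal
#' grey-matter mask, a contiguous planted partition of the grey matter into
#' `n_networks` functional networks (grown by simultaneous breadth-first
#' expansion from random seed voxels), and geometric vascular-territory
#' atlases — a lateralized coarse atlas (anterior/posterior x hemisphere,
#' 4 labels) and a fine atlas (6 wedges). The planted network labels are the
#' latent ground truth that downstream parcellation must recover.
#'
#' @param spec a [grid_spec()].
#' @param n_networks number of planted functional networks (>= 2).
#' @param seed integer seed; the world is a pure function of
#'   `(spec, n_networks, seed)`.
#' @return an object of class `brain_world` with fields `spec`, `gm_mask`,
#'   `vascular_labels_coarse`, `vascular_labels_fine`, `planted_networks`,
#'   `seed`.
#' @export
generate_world <- function(spec, n_networks, seed) {
  stopifnot(inherits(spec, "grid_spec"), n_networks >= 2)
  dims <- spec$dims

  # ellipsoidal grey-matter blob centred in the grid
  cx <- (dims + 1) / 2
  ax <- 0.42 * dims
  co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  inside <- ((co[, 1] - cx[1]) / ax[1])^2 + ((co[, 2] - cx[2]) / ax[2])^2 +
    ((co[, 3] - cx[3]) / ax[3])^2 <= 1
  gm <- array(0L, dims)
  gm[co[inside, , drop = FALSE]] <- 1L
  nvox <- sum(gm)
  if (nvox == 0L) stop("grey matter mask is empty for this grid")
  if (n_networks > nvox / 32) {
    stop("grid too small to host ", n_networks, " networks (",
         nvox, " grey voxels; need >= 32 per network)")
  }

  gm_idx <- which(gm == 1L)
  gm_co <- vox_coords(gm)

  planted <- with_seed(derive_seed(seed, "world/networks"), {
    lab <- array(0L, dims)
    seeds <- sample(gm_idx, n_networks)
    lab[seeds] <- seq_len(n_networks)
    # simultaneous BFS growth over 6-connectivity => contiguous cells
    offs <- neighbour_offsets(6)
    queue <- sample(seeds) # random service order
    while (length(queue) > 0L) {
      cur <- queue[1L]
      queue <- queue[-1L]
      cc <- arrayInd(cur, dims)
      nb <- sweep(offs, 2L, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
      lin <- lin[gm[lin] == 1L & lab[lin] == 0L]
      if (length(lin) > 0L) {
        lab[lin] <- lab[cur]
        queue <- c(queue, lin[sample.int(length(lin))])
      }
    }
    lab
  })

  # geometric vascular territories on the grey mask
  ymid <- stats::median(gm_co[, 2])
  anterior <- gm_co[, 2] <= ymid                # "anterior" half along y
  left <- gm_co[, 1] <= stats::median(gm_co[, 1])
  coarse <- array(0L, dims)
  coarse[gm_co] <- 1L + (!anterior) * 2L + (!left) * 1L  # 1..4

  ycut <- stats::quantile(gm_co[, 2], c(1 / 3, 2 / 3))
  third <- 1L + (gm_co[, 2] > ycut[1]) + (gm_co[, 2] > ycut[2])
  fine <- array(0L, dims)
  fine[gm_co] <- (third - 1L) * 2L + (!left) * 1L + 1L   # 1..6

  structure(list(spec = spec, gm_mask = gm,
                 vascular_labels_coarse = coarse,
                 vascular_labels_fine = fine,
                 planted_networks = planted, seed = seed),
            class = "brain_world")
}

#' @export
print.brain_world <- function(x, ...) {
  cat("<brain_world> grid", paste(x$spec$dims, collapse = "x"),
      "|", sum(x$gm_mask), "grey voxels |",
      length(setdiff(unique(as.vector(x$planted_networks)), 0L)),
      "planted networks | seed", x$seed, "\n")
  invisible(x)
}

#' Vascular-territory atlas at a chosen granularity
#'
#' `"two"` is the anterior/posterior atlas used as the simplest baseline
#' lesion representation (2 territories); `"coarse"` keeps laterality
#' (4 territories); `"fine"` has 6 arterial divisions.
#'
#' @param world a `brain_world`.
#' @param level `"two"`, `"coarse"`, or `"fine"`.
#' @return integer label volume (0 = background).
#' @export
vascular_atlas <- function(world, level = c("two", "coarse", "fine")) {
  level <- match.arg(level)
  switch(level,
         two = {
           v <- world$vascular_labels_coarse
           out <- array(0L, dim(v))
           out[v %in% c(1L, 2L)] <- 1L  # anterior
           out[v %in% c(3L, 4L)] <- 2L  # posterior
           out
         },
         coarse = world$vascular_labels_coarse,
         fine = world$vascular_labels_fine)
}

#' Mask of one planted network
#' @param world a `brain_world`.
#' @param network_id planted network label.
#' @return binary volume.
#' @export
network_mask <- function(world, network_id) {
  m <- array(0L, world$spec$dims)
  m[world$planted_networks == network_id] <- 1L
  if (sum(m) == 0L) stop("unknown network id: ", network_id)
  m
}
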