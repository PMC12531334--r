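#' Generate a synthetic lesion cohort
#'
#' Each lesion is grown by stochastic region growing (randomized
#' breadth-first expansion over 6-connectivity within the grey-matter mask)
#' from a seed voxel drawn proportionally to `frequency_map` (uniform over
#' the mask when `NULL`). The target size is uniform over `size_range_vox`.
#' Lesions are connected by construction; one lesion per synthetic patient.
#'
#' @param world a `brain_world`.
#' @param n_patients number of patients.
#' @param size_range_vox `c(min, max)` lesion size in voxels;
#'   `max <= grid volume / 4`.
#' @param frequency_map optional nonnegative volume biasing seed placement.
#' @param seed integer seed.
#' @return an object of class `lesion_cohort`: `patients` (list with
#'   `patient_id` and `lesion` binary volume), `seed`.
#' @export
generate_lesions <- function(world, n_patients, size_range_vox = c(10, 60),
                             frequency_map = NULL, seed = 1) {
  stopifnot(n_patients >= 1, length(size_range_vox) == 2,
            size_range_vox[1] >= 1,
            size_range_vox[1] <= size_range_vox[2])
  dims <- world$spec$dims
  if (size_range_vox[2] > prod(dims) / 4) {
    stop("maximum lesion size exceeds grid volume / 4")
  }
  gm_idx <- which(world$gm_mask == 1L)
  wts <- if (is.null(frequency_map)) rep(1, length(gm_idx)) else {
    stopifnot_same_shape(frequency_map, world$gm_mask)
    w <- frequency_map[gm_idx]
    if (any(w < 0)) stop("frequency_map must be nonnegative")
    if (sum(w) <= 0) stop("frequency_map is zero on the grey mask")
    w
  }
  offs <- neighbour_offsets(6)
  grow_one <- function(target) {
    for (attempt in 1:25) {
      start <- sample(gm_idx, 1L, prob = wts)
      les <- integer(0)
      frontier <- start
      in_lesion <- new.env(hash = TRUE)
      while (length(les) < target && length(frontier) > 0L) {
        pick <- sample.int(length(frontier), 1L)
        cur <- frontier[pick]
        frontier <- frontier[-pick]
        if (!is.null(in_lesion[[as.character(cur)]])) next
        in_lesion[[as.character(cur)]] <- TRUE
        les <- c(les, cur)
        cc <- arrayInd(cur, dims)
        nb <- sweep(offs, 2L, as.integer(cc), "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
          nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
          (nb[, 3] - 1L) * dims[1] * dims[2]
        lin <- lin[world$gm_mask[lin] == 1L]
        lin <- lin[vapply(as.character(lin),
                          function(k) is.null(in_lesion[[k]]), logical(1))]
        frontier <- c(frontier, lin)
      }
      if (length(les) >= target) return(les[seq_len(target)])
    }
    stop("could not grow a lesion of ", target, " voxels after 25 attempts")
  }
  patients <- with_seed(derive_seed(seed, "lesions"), {
    lapply(seq_len(n_patients), function(i) {
      sizes <- seq.int(size_range_vox[1], size_range_vox[2])
      target <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      les <- grow_one(target)
      vol <- array(0L, dims)
      vol[les] <- 1L
      list(patient_id = sprintf("p%04d", i), lesion = vol)
    })
  })
  structure(list(patients = patients, seed = seed), class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  sizes <- vapply(x$patients, function(p) sum(p$lesion), numeric(1))
  cat("<lesion_cohort>", length(x$patients), "patients | lesion size",
      min(sizes), "-", max(sizes), "voxels | seed", x$seed, "\n")
  invisible(x)
}

#' Generate surrogate tractography bundles
#'
#' Each bundle is a voxel path between two random grey-matter voxels,
#' produced by a guided random walk with per-subject directional jitter.
#' Consecutive path voxels differ by at most 1 on every axis, and all
#' voxels lie inside the grid. Only the output contract matters downstream:
#' bundles intersecting a lesion define its disconnection mask.
#'
#' @param world a `brain_world`.
#' @param n_subjects number of reference subjects (>= 2).
#' @param bundles_per_subject bundles per subject.
#' @param seed integer seed.
#' @return an object of class `tract_set`: `subjects`, a list (one per
#'   subject) of lists of n x 3 coordinate paths.
#' @export
generate_tracts <- function(world, n_subjects = 8, bundles_per_subject = 10,
                            seed = 1) {
  stopifnot(n_subjects >= 2, bundles_per_subject >= 1)
  dims <- world$spec$dims
  gm_co <- vox_coords(world$gm_mask)
  walk <- function(from, to, jitter) {
    path <- matrix(from, nrow = 1)
    cur <- from
    for (step in seq_len(4 * sum(dims))) {
      if (all(cur == to)) break
      dir <- sign(to - cur)
      noise <- sample(-1:1, 3, replace = TRUE,
                      prob = c(jitter, 1 - 2 * jitter, jitter))
      stp <- ifelse(stats::runif(3) < 0.75, dir, noise)
      nxt <- pmin(pmax(cur + stp, 1L), dims)
      if (!all(nxt == cur)) path <- rbind(path, nxt)
      cur <- nxt
    }
    path
  }
  subjects <- lapply(seq_len(n_subjects), function(s) {
    with_seed(derive_seed(seed, paste0("tracts/", s)), {
      jitter <- stats::runif(1, 0.05, 0.25) # per-subject jitter
      lapply(seq_len(bundles_per_subject), function(b) {
        ends <- gm_co[sample(nrow(gm_co), 2), , drop = FALSE]
        walk(as.integer(ends[1, ]), as.integer(ends[2, ]), jitter)
      })
    })
  })
  structure(list(subjects = subjects), class = "tract_set")
}

#' Compute a probabilistic disconnectome map for one lesion
#'
#' For each reference subject, every bundle intersecting the lesion marks
#' all of its voxels as disconnected; the subject's disconnection mask is
#' the union over intersecting bundles. The output voxel value is the
#' proportion of subjects whose mask covers that voxel. By default lesion
#' voxels themselves are set to 1 (the lesion core is affected by
#' convention; switchable).
#'
#' @param lesion binary volume.
#' @param tracts a `tract_set`.
#' @param lesion_value_one include lesion voxels at value 1 (default TRUE).
#' @return volume of values in `[0, 1]`.
#' @export
compute_disconnectome <- function(lesion, tracts, lesion_value_one = TRUE) {
  stopifnot(inherits(tracts, "tract_set"))
  if (length(tracts$subjects) == 0L) stop("empty tract set")
  dims <- dim(lesion)
  acc <- array(0, dims)
  for (subj in tracts$subjects) {
    mask <- array(FALSE, dims)
    hit <- FALSE
    for (path in subj) {
      lin <- path[, 1] + (path[, 2] - 1L) * dims[1] +
        (path[, 3] - 1L) * dims[1] * dims[2]
      if (any(lesion[lin] != 0)) {
        mask[lin] <- TRUE
        hit <- TRUE
      }
    }
    if (hit) acc <- acc + mask
  }
  out <- acc / length(tracts$subjects)
  if (lesion_value_one) out[lesion != 0] <- 1
  out
}
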