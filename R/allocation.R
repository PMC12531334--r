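#' Centroid of a binary mask
#'
#' Arithmetic mean of 0-based voxel coordinates.
#'
#' @param mask binary volume.
#' @return numeric 3-vector.
#' @export
centroid <- function(mask) {
  co <- vox_coords(mask)
  if (nrow(co) == 0) stop("empty mask has no centroid")
  colMeans(co) - 1
}

#' Axis of maximal centroid separation between the two subnetworks
#'
#' The observable-confounding axis: the coordinate axis along which the
#' centroids of the two responsiveness subnetworks differ the most
#' (ties to the lowest axis index). Axes are numbered 1..3.
#'
#' @param pair a `subnetwork_pair`.
#' @return list with `axis` (1..3), `c_A`, `c_B`.
#' @export
confounding_axis <- function(pair) {
  cA <- centroid(pair$mask_A)
  cB <- centroid(pair$mask_B)
  list(axis = which.max(abs(cA - cB)), c_A = cA, c_B = cB)
}

#' Allocate treatments under observable (lesion-location) confounding
#'
#' Patients are ranked by their lesion-centroid coordinate along the
#' confounding axis (ties broken by `patient_id`, stable). For
#' `b_obs <= 0.5` the probability of receiving B for the k-th ranked
#' patient is the k-th element of an evenly spaced sequence from
#' `0.5 - b_obs` to `0.5 + b_obs`; `b_obs = 0` is a randomized trial. For
#' `b_obs > 0.5`, a per-tail fraction `f = b_obs - 0.5` of ranked patients
#' at each extreme is allocated deterministically by their side of
#' `train_median` (below: A; at or above: B) — rank `k` is deterministic iff
#' its rank midpoint `(k - 0.5)/N` falls within `f` of either end, which is
#' continuous at `b_obs = 0.5` and fully deterministic at `b_obs = 1` — and
#' the interior patients receive probabilities evenly spaced over `[0, 1]`.
#'
#' @param coords per-patient lesion-centroid coordinate along the axis.
#' @param b_obs confounding strength in `[0, 1]`.
#' @param train_median median coordinate of the training fold (defaults to
#'   the median of `coords`).
#' @param seed integer seed for the Bernoulli draws.
#' @param patient_ids optional ids used for stable tie-breaking.
#' @return list with `w` (character vector of `"A"`/`"B"` in input order)
#'   and `rho` (per-patient probability of B; 0/1 for deterministic
#'   allocations).
#' @export
allocate_observable <- function(coords, b_obs, train_median = NULL,
                                seed = 1, patient_ids = NULL) {
  N <- length(coords)
  stopifnot(N >= 2)
  if (b_obs < 0 || b_obs > 1) stop("b_obs must lie in [0, 1]")
  if (is.null(train_median)) train_median <- stats::median(coords)
  if (is.null(patient_ids)) patient_ids <- seq_len(N)
  ord <- order(coords, patient_ids) # stable, ties by id
  rho_ranked <- numeric(N)
  det_ranked <- logical(N)
  if (b_obs <= 0.5) {
    rho_ranked <- seq(0.5 - b_obs, 0.5 + b_obs, length.out = N)
  } else {
    f <- b_obs - 0.5
    mid <- (seq_len(N) - 0.5) / N
    det_ranked <- mid <= f | mid >= 1 - f
    interior <- which(!det_ranked)
    if (length(interior) == 1L) {
      rho_ranked[interior] <- 0.5
    } else if (length(interior) > 1L) {
      rho_ranked[interior] <- seq(0, 1, length.out = length(interior))
    }
  }
  w_ranked <- character(N)
  if (any(det_ranked)) {
    side_b <- coords[ord][det_ranked] >= train_median
    w_ranked[det_ranked] <- ifelse(side_b, "B", "A")
    rho_ranked[det_ranked] <- as.numeric(side_b)
  }
  sto <- which(!det_ranked)
  if (length(sto) > 0) {
    draws <- with_seed(derive_seed(seed, "alloc/obs"),
                       stats::runif(length(sto)))
    w_ranked[sto] <- ifelse(draws < rho_ranked[sto], "B", "A")
  }
  w <- character(N); rho <- numeric(N)
  w[ord] <- w_ranked
  rho[ord] <- rho_ranked
  list(w = w, rho = rho)
}

#' Allocate treatments under unobservable confounding
#'
#' Allocation depends on the hidden optimal treatment: for single
#' responders, `W = w_star` with probability `b_unobs`, else the other arm;
#' `b_unobs = 0.5` is independent of the truth. Dual responders (`s = 0`,
#' for whom `w_star` is undefined) receive a fair-coin allocation.
#'
#' @param hidden a `responsiveness_records` data.frame.
#' @param b_unobs probability of allocating the truly optimal arm.
#' @param seed integer seed.
#' @return character vector of `"A"`/`"B"`.
#' @export
allocate_unobservable <- function(hidden, b_unobs, seed = 1) {
  if (b_unobs < 0 || b_unobs > 1) stop("b_unobs must lie in [0, 1]")
  n <- nrow(hidden)
  with_seed(derive_seed(seed, "alloc/unobs"), {
    u <- stats::runif(n)
    other <- ifelse(hidden$w_star == "A", "B", "A")
    ifelse(hidden$s == 0,
           ifelse(stats::runif(n) < 0.5, "B", "A"),
           ifelse(u < b_unobs, hidden$w_star, other))
  })
}

#' Sample observed outcomes under the TE/RE noise model
#'
#' `y_i ~ Bernoulli(expected_outcomes(record_i, w_i, noise))`,
#' independently. At `TE = 1, RE = 0` the outcome is deterministic:
#' favourable iff the allocated treatment is suitable.
#'
#' @param hidden a `responsiveness_records` data.frame.
#' @param w allocation vector (`"A"`/`"B"`).
#' @param noise a `noise_config`.
#' @param seed integer seed.
#' @return integer vector of 0/1 outcomes.
#' @export
sample_outcomes <- function(hidden, w, noise, seed = 1) {
  stopifnot(nrow(hidden) == length(w))
  p <- expected_outcomes(hidden, w, noise)
  with_seed(derive_seed(seed, "outcomes"),
            stats::rbinom(length(p), 1L, p))
}

#' Check whether a trial dataset can support model fitting
#'
#' A dataset is degenerate — the grid's skipped cells — iff a treatment arm
#' is empty, the outcome is single-class overall (S-learner requirement), or
#' single-class within an arm (T-learner requirement).
#'
#' @param w allocation vector.
#' @param y outcome vector.
#' @param learner `"S"` or `"T"`.
#' @return `TRUE` when fittable, `FALSE` when degenerate.
#' @export
check_fittable <- function(w, y, learner = c("T", "S")) {
  learner <- match.arg(learner)
  if (length(unique(w)) < 2) return(FALSE)
  if (length(unique(y)) < 2) return(FALSE)
  if (learner == "T") {
    for (arm in c("A", "B")) {
      if (length(unique(y[w == arm])) < 2) return(FALSE)
    }
  }
  TRUE
}
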