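#' Construct a subnetwork pair (internal constructor with invariant checks)
#'
#' @param network_id network label.
#' @param mask_A,mask_B binary volumes; must be disjoint, nonempty, and
#'   together exactly cover `network_mask`.
#' @param network_mask the parent network mask.
#' @param provenance descriptor (e.g. receptor names or cluster ids).
#' @param criterion `"receptome"` or `"transcriptome"`.
#' @return an object of class `subnetwork_pair`.
#' @keywords internal
new_subnetwork_pair <- function(network_id, mask_A, mask_B, network_mask,
                                provenance, criterion) {
  stopifnot_same_shape(mask_A, mask_B)
  if (sum(mask_A) == 0 || sum(mask_B) == 0) {
    stop("degenerate subdivision: one subnetwork side is empty")
  }
  if (any(mask_A != 0 & mask_B != 0)) stop("subnetwork sides overlap")
  if (!all((mask_A != 0 | mask_B != 0) == (network_mask != 0))) {
    stop("subnetwork sides do not partition the network")
  }
  structure(list(network_id = network_id, mask_A = mask_A, mask_B = mask_B,
                 provenance = provenance, criterion = criterion),
            class = "subnetwork_pair")
}

#' @export
print.subnetwork_pair <- function(x, ...) {
  cat("<subnetwork_pair> network", x$network_id, "|", x$criterion, "|",
      sum(x$mask_A), "+", sum(x$mask_B), "voxels |",
      paste(unlist(x$provenance), collapse = " vs "), "\n")
  invisible(x)
}

#' Subdivide a network by receptor preponderance
#'
#' Receptor preponderance within the network is the Dice coefficient
#' between the network mask and the binarized receptor map (`z > z_threshold`,
#' default 0). The two most preponderant receptors are selected, and each
#' network voxel is assigned to whichever of the two has the greater z-score
#' there (ties to the first-ranked receptor). An empty side is an error; the
#' caller may drop such networks.
#'
#' @param network_mask binary volume.
#' @param receptors a `receptor_set`.
#' @param network_id label recorded on the pair.
#' @param z_threshold binarization threshold for preponderance (default 0).
#' @return a `subnetwork_pair` with `criterion = "receptome"`.
#' @export
subdivide_receptome <- function(network_mask, receptors, network_id = NA,
                                z_threshold = 0) {
  stopifnot(inherits(receptors, "receptor_set"),
            length(receptors$zmaps) >= 2)
  if (sum(network_mask) == 0) stop("empty network mask")
  prep <- vapply(receptors$zmaps, function(z) {
    bin <- array(0L, dim(z)); bin[z > z_threshold] <- 1L
    if (sum(bin) == 0) return(0)
    dice(network_mask, bin)
  }, numeric(1))
  top2 <- order(-prep)[1:2]
  z1 <- receptors$zmaps[[top2[1]]]
  z2 <- receptors$zmaps[[top2[2]]]
  in_net <- network_mask != 0
  mask_A <- array(0L, dim(network_mask))
  mask_B <- array(0L, dim(network_mask))
  a_side <- in_net & (z1 >= z2) # ties go to the first-ranked receptor
  mask_A[a_side] <- 1L
  mask_B[in_net & !a_side] <- 1L
  new_subnetwork_pair(network_id, mask_A, mask_B, network_mask,
                      provenance = receptors$names[top2],
                      criterion = "receptome")
}

#' Subdivide a network by transcriptome clustering
#'
#' In-network sample sites are two-way agglomeratively clustered on their
#' expression profiles (correlation distance, average linkage). For each
#' smoothing bandwidth in `sigma_grid`, each cluster's site indicator is
#' convolved with an isotropic Gaussian of sd sigma and every network voxel
#' is assigned to the cluster with the greater smoothed value. The bandwidth
#' minimizing `J(sigma) = |n_A - n_B| / (n_A + n_B) +
#' lambda * (components_A + components_B - 2)` is retained, balancing the
#' two classes against spatial fragmentation.
#'
#' @param network_mask binary volume.
#' @param samples a `transcriptome_samples`.
#' @param sigma_grid positive smoothing bandwidths (voxels) to search.
#' @param network_id label recorded on the pair.
#' @param lambda component-count penalty weight (default 0.05).
#' @param connectivity connectivity for the component count (default 26).
#' @return a `subnetwork_pair` with `criterion = "transcriptome"`.
#' @export
subdivide_transcriptome <- function(network_mask, samples,
                                    sigma_grid = c(1, 2, 3, 4),
                                    network_id = NA, lambda = 0.05,
                                    connectivity = 26) {
  stopifnot(inherits(samples, "transcriptome_samples"),
            length(sigma_grid) >= 1, all(sigma_grid > 0))
  dims <- dim(network_mask)
  in_net <- network_mask[samples$sites] != 0
  if (sum(in_net) < 4) stop("fewer than 4 transcriptome samples in network")
  sites <- samples$sites[in_net, , drop = FALSE]
  prof <- samples$profiles[in_net, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(prof)))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2)

  in_mask <- network_mask != 0
  best <- NULL
  for (sg in sigma_grid) {
    fa <- gaussian_smooth3d(vol_from_coords(sites[cl == 1, , drop = FALSE],
                                            dims), sg)
    fb <- gaussian_smooth3d(vol_from_coords(sites[cl == 2, , drop = FALSE],
                                            dims), sg)
    a_side <- in_mask & (fa >= fb)
    mask_A <- array(0L, dims); mask_A[a_side] <- 1L
    mask_B <- array(0L, dims); mask_B[in_mask & !a_side] <- 1L
    nA <- sum(mask_A); nB <- sum(mask_B)
    if (nA == 0 || nB == 0) next # degenerate sigma skipped
    comps <- nrow_components(mask_A, connectivity) +
      nrow_components(mask_B, connectivity)
    J <- abs(nA - nB) / (nA + nB) + lambda * (comps - 2)
    if (is.null(best) || J < best$J) {
      best <- list(J = J, sigma = sg, mask_A = mask_A, mask_B = mask_B)
    }
  }
  if (is.null(best)) stop("all sigma values gave a degenerate subdivision")
  new_subnetwork_pair(network_id, best$mask_A, best$mask_B, network_mask,
                      provenance = list(clusters = c(1, 2), sigma = best$sigma),
                      criterion = "transcriptome")
}

nrow_components <- function(mask, connectivity = 26) {
  max(label_components(mask, connectivity))
}
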