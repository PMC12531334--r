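#' Agglomerative functional parcellation of grey-matter voxels
#'
#' Clusters the voxel columns of a term-by-voxel association matrix by
#' correlation distance (1 - Pearson correlation of association profiles)
#' with average linkage, and cuts the tree to exactly `K` networks. The
#' full merge history is returned so the hierarchy can be re-cut at any
#' threshold without re-clustering.
#'
#' @param term_matrix a `term_matrix`.
#' @param K number of networks (2 <= K <= number of voxels).
#' @param method linkage method passed to [stats::hclust()].
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param dims grid dimensions for label volumes (defaults to the voxel
#'   bounding box; pass `world$spec$dims` to align with world volumes).
#' @return an object of class `parcellation`: `labels` (integer volume over
#'   the voxel index), `K`, `linkage_record` (merge matrix + heights),
#'   `voxel_index`, `dims`.
#' @export
cluster_voxels <- function(term_matrix, K, method = "average",
                           distance = c("correlation", "euclidean"),
                           dims = NULL) {
  distance <- match.arg(distance)
  S <- term_matrix$scores
  V <- ncol(S)
  stopifnot(K >= 2, K <= V)
  d <- if (distance == "correlation") {
    sds <- apply(S, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1]
      stop("constant association column at voxel (",
           paste(term_matrix$voxel_index[bad, ], collapse = ","),
           "): correlation distance undefined")
    }
    stats::as.dist(1 - stats::cor(S))
  } else {
    stats::dist(t(S))
  }
  hc <- stats::hclust(d, method = method)
  if (any(diff(hc$height) < -1e-8)) {
    warning("non-monotone linkage heights; tree cut may be ambiguous")
  }
  labels <- stats::cutree(hc, k = K)
  if (is.null(dims)) dims <- apply(term_matrix$voxel_index, 2, max)
  structure(list(labels = labels, K = K,
                 linkage_record = list(merge = hc$merge, height = hc$height),
                 voxel_index = term_matrix$voxel_index,
                 dims = dims),
            class = "parcellation")
}

#' Label volume of a parcellation
#' @param parc a `parcellation`.
#' @param dims grid dimensions (defaults to the bounding box of the voxels).
#' @return integer volume; 0 outside the parcellated voxels.
#' @export
parcellation_volume <- function(parc, dims = NULL) {
  if (is.null(dims)) dims <- parc$dims
  vol <- array(0L, dims)
  vol[parc$voxel_index] <- parc$labels
  vol
}

#' Reassign voxels of undersized connected components
#'
#' Connected components (26-connectivity by default) of each network label
#' smaller than `min_volume_vox` voxels are dissolved: each of their voxels
#' is reassigned to the majority label among its `k_neighbours` nearest
#' (Euclidean, voxel coordinates) voxels that do not belong to any
#' undersized component. A single pass; the voxel set is conserved.
#'
#' @param parc a `parcellation`.
#' @param min_volume_vox minimum component volume kept (default 64 = 4^3).
#' @param k_neighbours neighbours for the majority vote (default 5).
#' @param connectivity 26 (default) or 6.
#' @return a `parcellation` with cleaned labels.
#' @export
clean_small_components <- function(parc, min_volume_vox = 64,
                                   k_neighbours = 5, connectivity = 26) {
  stopifnot(min_volume_vox >= 1)
  dims <- parc$dims
  labels <- parc$labels
  coords <- parc$voxel_index
  undersized <- rep(FALSE, length(labels))
  for (lb in sort(unique(labels))) {
    sel <- labels == lb
    mask <- vol_from_coords(coords[sel, , drop = FALSE], dims)
    comp <- label_components(mask, connectivity)
    cl <- comp[coords[sel, , drop = FALSE]]
    sizes <- table(cl)
    small <- as.integer(names(sizes)[sizes < min_volume_vox])
    if (length(small) > 0) undersized[which(sel)[cl %in% small]] <- TRUE
  }
  if (!any(undersized)) return(parc)
  if (all(undersized)) stop("all voxels lie in undersized components; no donor voxels")
  donors <- which(!undersized)
  donor_coords <- coords[donors, , drop = FALSE]
  donor_labels <- labels[donors]
  new_labels <- labels
  for (i in which(undersized)) {
    new_labels[i] <- knn_majority_label(coords[i, ], donor_coords,
                                        donor_labels, k_neighbours)
  }
  parc$labels <- new_labels
  parc$K <- length(unique(new_labels))
  parc
}

#' Rank terms by similarity to a network
#'
#' Similarity is the mean association score of the term over the network's
#' voxels (or the cosine between the term's score profile and the network
#' indicator). Ties keep the original term order (stable sort).
#'
#' @param parc a `parcellation`.
#' @param term_matrix the `term_matrix` that produced it.
#' @param network_id network label to rank against.
#' @param similarity `"mean"` (default) or `"cosine"`.
#' @return data.frame with columns `term`, `score`, ordered nonincreasing.
#' @export
rank_terms <- function(parc, term_matrix, network_id,
                       similarity = c("mean", "cosine")) {
  similarity <- match.arg(similarity)
  sel <- parc$labels == network_id
  if (!any(sel)) stop("unknown network id: ", network_id)
  S <- term_matrix$scores
  score <- if (similarity == "mean") {
    rowMeans(S[, sel, drop = FALSE])
  } else {
    ind <- as.numeric(sel)
    as.vector(S %*% ind) / (sqrt(rowSums(S^2)) * sqrt(sum(ind)) + 1e-12)
  }
  ord <- order(-score) # stable: ties keep term order
  data.frame(term = term_matrix$terms[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; errors when both masks are empty (undefined).
#'
#' @param mask_a,mask_b binary volumes of identical shape.
#' @return real in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot_same_shape(mask_a, mask_b)
  a <- sum(mask_a != 0); b <- sum(mask_b != 0)
  if (a + b == 0) stop("Dice undefined: both masks empty")
  2 * sum(mask_a != 0 & mask_b != 0) / (a + b)
}
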