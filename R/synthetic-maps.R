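#' Generate a synthetic term-by-voxel association matrix
#'
#' Emulates meta-analytic functional association maps: each term belongs to
#' one planted network and scores `effect` on that network's voxels plus
#' Gaussian noise, so the planted parcellation is recoverable by clustering
#' the voxel columns.
#'
#' @param world a `brain_world`.
#' @param terms_per_network number of terms per planted network.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param effect membership signal magnitude (> 0 for recoverable structure).
#' @param seed integer seed.
#' @return an object of class `term_matrix`: `terms` (character),
#'   `scores` (T x V matrix), `voxel_index` (V x 3 coordinates).
#' @export
generate_term_matrix <- function(world, terms_per_network, noise_sd = 0.1,
                                 effect = 1, seed = 1) {
  stopifnot(terms_per_network >= 1, noise_sd >= 0, effect > 0)
  vox <- vox_coords(world$gm_mask)
  net <- world$planted_networks[vox]
  ids <- sort(unique(net))
  terms <- unlist(lapply(ids, function(k) {
    paste0("net", k, "_term", seq_len(terms_per_network))
  }))
  term_net <- rep(ids, each = terms_per_network)
  scores <- with_seed(derive_seed(seed, "terms"), {
    base <- effect * outer(term_net, net, "==")
    if (noise_sd > 0) base <- base + matrix(
      stats::rnorm(length(base), sd = noise_sd), nrow = nrow(base))
    base
  })
  rownames(scores) <- terms
  structure(list(terms = terms, term_network = term_net, scores = scores,
                 voxel_index = vox), class = "term_matrix")
}

#' Generate synthetic receptor density z-maps
#'
#' Each map is an independent smoothed Gaussian random field standardized to
#' zero mean and unit variance over the grey-matter mask, standing in for
#' group-average PET receptor z-score maps.
#'
#' @param world a `brain_world`.
#' @param n_receptors number of receptor maps (>= 2).
#' @param smoothness_vox Gaussian smoothing sd in voxels (> 0).
#' @param seed integer seed.
#' @return an object of class `receptor_set`: `names`, `zmaps` (list of
#'   volumes; values outside the grey mask are 0).
#' @export
generate_receptors <- function(world, n_receptors = 4, smoothness_vox = 2,
                               seed = 1) {
  stopifnot(n_receptors >= 2, smoothness_vox > 0)
  dims <- world$spec$dims
  gm <- world$gm_mask == 1L
  zmaps <- lapply(seq_len(n_receptors), function(r) {
    with_seed(derive_seed(seed, paste0("receptor/", r)), {
      f <- array(stats::rnorm(prod(dims)), dims)
      f <- gaussian_smooth3d(f, smoothness_vox)
      v <- f[gm]
      f[!gm] <- 0
      f[gm] <- (v - mean(v)) / stats::sd(v)
      f
    })
  })
  structure(list(names = paste0("receptor", seq_len(n_receptors)),
                 zmaps = zmaps), class = "receptor_set")
}

#' Generate synthetic transcriptome sample sites and expression profiles
#'
#' Emulates spatially sampled microarray data: sites are drawn inside each
#' planted network and carry a planted two-way split aligned with a spatial
#' half of the network; expression profiles are a split-specific mean shift
#' of magnitude `split_effect` plus unit Gaussian noise.
#'
#' @param world a `brain_world`.
#' @param sites_per_network number of sample sites per network (>= 4).
#' @param n_genes number of genes per profile.
#' @param split_effect magnitude of the between-split mean shift.
#' @param seed integer seed.
#' @return an object of class `transcriptome_samples`: `sites` (S x 3
#'   coordinates), `profiles` (S x G), `planted_split` (1/2),
#'   `network` (planted network id per site).
#' @export
generate_transcriptome <- function(world, sites_per_network = 10,
                                   n_genes = 50, split_effect = 5, seed = 1) {
  stopifnot(sites_per_network >= 4, n_genes >= 1)
  ids <- sort(setdiff(unique(as.vector(world$planted_networks)), 0L))
  sites <- NULL; split <- integer(0); netv <- integer(0)
  for (k in ids) {
    co <- vox_coords(network_mask(world, k))
    if (nrow(co) < sites_per_network) {
      stop("network ", k, " too small to place ", sites_per_network, " sites")
    }
    pick <- with_seed(derive_seed(seed, paste0("tx/sites/", k)),
                      sample(nrow(co), sites_per_network))
    co <- co[pick, , drop = FALSE]
    # split along the network's widest spatial axis at the site median
    ax <- which.max(apply(co, 2, function(u) diff(range(u))))
    side <- ifelse(co[, ax] <= stats::median(co[, ax]), 1L, 2L)
    if (length(unique(side)) == 1L) side[seq_len(floor(length(side) / 2))] <- 2L
    sites <- rbind(sites, co)
    split <- c(split, side)
    netv <- c(netv, rep(k, nrow(co)))
  }
  profiles <- with_seed(derive_seed(seed, "tx/profiles"), {
    g_half <- max(1L, floor(n_genes / 2))
    shift <- matrix(0, nrow(sites), n_genes)
    shift[split == 1L, seq_len(g_half)] <- split_effect
    if (g_half < n_genes) {
      shift[split == 2L, seq.int(g_half + 1L, n_genes)] <- split_effect
    }
    shift + matrix(stats::rnorm(nrow(sites) * n_genes), nrow(sites))
  })
  structure(list(sites = sites, profiles = profiles, planted_split = split,
                 network = netv), class = "transcriptome_samples")
}
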