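test_that("cluster_voxels recovers the planted partition at low noise", {
  w <- fx_world()
  tm <- generate_term_matrix(w, terms_per_network = 5, noise_sd = 0.1,
                             effect = 1, seed = 4)
  parc <- cluster_voxels(tm, K = 4, dims = w$spec$dims)
  planted <- w$planted_networks[tm$voxel_index]
  # partition agreement up to label permutation: the cross-table must have
  # exactly one nonzero cell per row and per column
  ct <- table(parc$labels, planted)
  expect_identical(sum(ct > 0), 4L)
  expect_true(all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1))
})

test_that("cluster_voxels validates inputs and names bad voxels", {
  w <- fx_world()
  tm <- generate_term_matrix(w, 3, noise_sd = 0.1, seed = 4)
  expect_error(cluster_voxels(tm, K = 1), "K")
  tm_bad <- tm
  tm_bad$scores[, 7] <- 0  # constant column
  err <- tryCatch(cluster_voxels(tm_bad, K = 4), error = conditionMessage)
  expect_match(err, "constant association column")
  expect_match(err, paste(tm$voxel_index[7, ], collapse = ","), fixed = TRUE)
  # euclidean distance tolerates constant columns
  parc <- cluster_voxels(tm_bad, K = 4, distance = "euclidean",
                         dims = w$spec$dims)
  expect_equal(parc$K, 4)
})

test_that("parcellation_volume places labels at voxel coordinates", {
  w <- fx_world()
  tm <- generate_term_matrix(w, 3, noise_sd = 0.1, seed = 4)
  parc <- cluster_voxels(tm, K = 4, dims = w$spec$dims)
  vol <- parcellation_volume(parc)
  expect_identical(dim(vol), w$spec$dims)
  expect_identical(as.integer(vol[tm$voxel_index]), as.integer(parc$labels))
  expect_true(all(vol[w$gm_mask == 0L] == 0L))
})

test_that("clean_small_components dissolves islands and conserves voxels", {
  # hand-built parcellation: label 1 occupies a slab, label 2 another, and a
  # single label-2 voxel sits isolated deep inside label 1's slab
  dims <- c(10L, 10L, 10L)
  co <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:5))
  labels <- rep(1L, nrow(co))
  labels[co[, 3] >= 4] <- 2L
  island <- which(co[, 1] == 5 & co[, 2] == 5 & co[, 3] == 2)
  labels[island] <- 2L
  parc <- structure(list(labels = labels, K = 2L,
                         linkage_record = NULL, voxel_index = co,
                         dims = dims), class = "parcellation")
  cleaned <- clean_small_components(parc, min_volume_vox = 8)
  expect_identical(cleaned$labels[island], 1L)          # island reassigned
  expect_identical(cleaned$labels[-island], labels[-island])
  expect_identical(nrow(cleaned$voxel_index), nrow(co)) # voxels conserved
  # idempotent on its own output
  expect_identical(clean_small_components(cleaned, min_volume_vox = 8)$labels,
                   cleaned$labels)
  # no undersized components -> untouched
  expect_identical(clean_small_components(parc, min_volume_vox = 1)$labels,
                   labels)
})

test_that("rank_terms ranks planted terms first and zero terms last", {
  # hand-built term matrix over 6 voxels in two networks
  co <- cbind(x = 1:6, y = rep(1L, 6), z = rep(1L, 6))
  scores <- rbind(netA = c(1, 1, 1, 0, 0, 0),
                  netB = c(0, 0, 0, 1, 1, 1),
                  zero = c(0, 0, 0, 0, 0, 0))
  tm <- structure(list(terms = rownames(scores), scores = scores,
                       voxel_index = co), class = "term_matrix")
  parc <- structure(list(labels = c(1L, 1L, 1L, 2L, 2L, 2L), K = 2L,
                         linkage_record = NULL, voxel_index = co,
                         dims = c(6L, 1L, 1L)), class = "parcellation")
  rk <- rank_terms(parc, tm, network_id = 1)
  expect_identical(rk$term[1], "netA")
  expect_identical(rk$term[3], "zero")
  expect_true(all(diff(rk$score) <= 0))
  rk2 <- rank_terms(parc, tm, network_id = 2, similarity = "cosine")
  expect_identical(rk2$term[1], "netB")
  expect_error(rank_terms(parc, tm, network_id = 9), "unknown network id")
})

test_that("dice matches hand arithmetic and its invariants", {
  dims <- c(4L, 4L, 4L)
  a <- array(0L, dims); b <- array(0L, dims)
  a[1:4] <- 1L                       # |A| = 4
  b[3:8] <- 1L                       # |B| = 6, |A n B| = 2
  expect_equal(dice(a, b), 0.4)      # 2*2 / (4+6)
  expect_equal(dice(a, a), 1)
  d <- array(0L, dims); d[60:64] <- 1L
  expect_equal(dice(a, d), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(array(0L, dims), array(0L, dims)), "both masks empty")
  expect_error(dice(a, array(0L, c(4L, 4L, 5L))), "shapes differ")
})

test_that("receptome subdivision selects the two most preponderant receptors", {
  w <- fx_world()
  pair <- fx_pair()
  expect_s3_class(pair, "subnetwork_pair")
  expect_identical(pair$criterion, "receptome")
  nm <- network_mask(w, 2)
  # exact partition of the network
  expect_true(all((pair$mask_A == 1L | pair$mask_B == 1L) == (nm == 1L)))
  expect_false(any(pair$mask_A == 1L & pair$mask_B == 1L))
  expect_gt(sum(pair$mask_A), 0); expect_gt(sum(pair$mask_B), 0)
  # provenance carries the two top receptors by z>0 Dice preponderance
  rs <- fx_receptors()
  prep <- vapply(rs$zmaps, function(z) {
    bin <- array(0L, dim(z)); bin[z > 0] <- 1L
    dice(nm, bin)
  }, numeric(1))
  expect_setequal(pair$provenance, rs$names[order(-prep)[1:2]])
  # per-voxel assignment follows the greater z of the two selected maps
  top <- match(pair$provenance, rs$names)
  z1 <- rs$zmaps[[top[1]]]; z2 <- rs$zmaps[[top[2]]]
  inside <- nm == 1L
  expect_true(all((z1 >= z2)[inside] == (pair$mask_A == 1L)[inside]))
})

test_that("transcriptome subdivision balances sides and partitions exactly", {
  w <- fx_world()
  tx <- generate_transcriptome(w, sites_per_network = 12, n_genes = 30,
                               split_effect = 5, seed = 6)
  nm <- network_mask(w, 3)
  pair <- subdivide_transcriptome(nm, tx, network_id = 3)
  expect_identical(pair$criterion, "transcriptome")
  expect_true(all((pair$mask_A == 1L | pair$mask_B == 1L) == (nm == 1L)))
  expect_false(any(pair$mask_A == 1L & pair$mask_B == 1L))
  expect_true(pair$provenance$sigma %in% c(1, 2, 3, 4))
  expect_error(subdivide_transcriptome(nm, tx, sigma_grid = numeric(0)))
})

test_that("subnetwork pair constructor enforces its invariants", {
  dims <- c(6L, 6L, 6L)
  net <- array(0L, dims); net[1:10] <- 1L
  a <- array(0L, dims); a[1:5] <- 1L
  b <- array(0L, dims); b[6:10] <- 1L
  p <- vitrials:::new_subnetwork_pair(1, a, b, net, list("x", "y"), "receptome")
  expect_s3_class(p, "subnetwork_pair")
  bad <- b; bad[5] <- 1L
  expect_error(vitrials:::new_subnetwork_pair(1, a, bad, net, NULL, "receptome"),
               "overlap")
  short <- array(0L, dims); short[6:9] <- 1L
  expect_error(vitrials:::new_subnetwork_pair(1, a, short, net, NULL,
                                              "receptome"),
               "partition")
  empty <- array(0L, dims)
  expect_error(vitrials:::new_subnetwork_pair(1, a, empty, net, NULL,
                                              "receptome"),
               "empty")
})
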