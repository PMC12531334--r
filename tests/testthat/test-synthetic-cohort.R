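test_that("grid_spec validates its arguments", {
  sp <- grid_spec(c(16, 16, 16), voxel_size_mm = 2)
  expect_s3_class(sp, "grid_spec")
  expect_identical(sp$dims, c(16L, 16L, 16L))
  expect_error(grid_spec(c(4, 16, 16)), "dims")
  expect_error(grid_spec(c(16, 16)), "length")
  expect_error(grid_spec(c(16, 16, 16), voxel_size_mm = 0))
})

test_that("generate_world is deterministic and partitions the grey matter", {
  w1 <- fx_world()
  w2 <- generate_world(grid_spec(c(16, 16, 16)), n_networks = 4, seed = 1)
  expect_identical(w1$planted_networks, w2$planted_networks)
  expect_identical(w1$gm_mask, w2$gm_mask)
  # a different seed moves the planted partition
  w3 <- generate_world(grid_spec(c(16, 16, 16)), n_networks = 4, seed = 2)
  expect_false(identical(w1$planted_networks, w3$planted_networks))
  # networks exactly cover the grey matter, nothing outside
  expect_true(all((w1$planted_networks > 0) == (w1$gm_mask == 1)))
  expect_setequal(setdiff(unique(as.vector(w1$planted_networks)), 0L), 1:4)
})

test_that("planted networks are 6-connected", {
  w <- fx_world()
  for (k in 1:4) {
    expect_identical(max(label_components(network_mask(w, k), 6)), 1L)
  }
})

test_that("vascular atlases have the advertised label sets", {
  w <- fx_world()
  gm <- w$gm_mask == 1
  expect_setequal(unique(as.vector(vascular_atlas(w, "two")[gm])), 1:2)
  expect_setequal(unique(as.vector(vascular_atlas(w, "coarse")[gm])), 1:4)
  expect_setequal(unique(as.vector(vascular_atlas(w, "fine")[gm])), 1:6)
  # the 2-territory atlas is the anterior/posterior collapse of the coarse one
  two <- vascular_atlas(w, "two")
  coarse <- vascular_atlas(w, "coarse")
  expect_true(all(two[coarse %in% c(1L, 2L)] == 1L))
  expect_true(all(two[coarse %in% c(3L, 4L)] == 2L))
  expect_true(all(two[!gm] == 0L))
})

test_that("network_mask errors on unknown ids", {
  expect_error(network_mask(fx_world(), 99), "unknown network id")
})

test_that("term matrix carries the planted block structure", {
  w <- fx_world()
  tm <- generate_term_matrix(w, terms_per_network = 3, noise_sd = 0,
                             effect = 2, seed = 4)
  expect_identical(dim(tm$scores),
                   c(12L, as.integer(sum(w$gm_mask))))
  expect_identical(length(tm$terms), 12L)
  # at zero noise, scores are exactly effect * membership
  net_of_vox <- w$planted_networks[tm$voxel_index]
  expected <- 2 * outer(tm$term_network, net_of_vox, "==")
  expect_equal(unname(tm$scores), unname(expected))
  expect_error(generate_term_matrix(w, 2, noise_sd = -1), "noise_sd")
})

test_that("receptor maps are standardized fields on the grey mask", {
  w <- fx_world()
  rs <- fx_receptors()
  expect_length(rs$zmaps, 4)
  gm <- w$gm_mask == 1
  for (z in rs$zmaps) {
    expect_equal(mean(z[gm]), 0, tolerance = 1e-12)
    expect_equal(sd(z[gm]), 1, tolerance = 1e-12)
    expect_true(all(z[!gm] == 0))
  }
  rs2 <- generate_receptors(w, 4, 2, seed = 3)
  expect_identical(rs$zmaps, rs2$zmaps)
  expect_error(generate_receptors(w, n_receptors = 1))
})

test_that("transcriptome sites live inside their networks with both splits", {
  w <- fx_world()
  tx <- generate_transcriptome(w, sites_per_network = 8, n_genes = 20,
                               split_effect = 5, seed = 6)
  expect_identical(nrow(tx$sites), 32L)
  expect_identical(dim(tx$profiles), c(32L, 20L))
  site_net <- w$planted_networks[tx$sites]
  expect_identical(as.integer(site_net), as.integer(tx$network))
  for (k in 1:4) {
    expect_setequal(unique(tx$planted_split[tx$network == k]), 1:2)
  }
})

test_that("lesions are connected, in-mask, and size-bounded", {
  w <- fx_world()
  les <- generate_lesions(w, n_patients = 8, size_range_vox = c(12, 30),
                          seed = 13)
  for (p in les$patients) {
    sz <- sum(p$lesion)
    expect_gte(sz, 12); expect_lte(sz, 30)
    expect_true(all(w$gm_mask[p$lesion == 1L] == 1L))
    expect_identical(max(label_components(p$lesion, 6)), 1L)
  }
  les2 <- generate_lesions(w, 8, c(12, 30), seed = 13)
  expect_identical(les$patients, les2$patients)
  expect_error(generate_lesions(w, 2, c(10, prod(w$spec$dims))),
               "grid volume")
})

test_that("a frequency map biases lesion seeding", {
  w <- fx_world()
  # all weight on one network: every lesion must start there (and, being
  # small, stay nearby — assert intersection with the favoured network)
  fm <- array(0, w$spec$dims)
  fm[network_mask(w, 1) == 1L] <- 1
  les <- generate_lesions(w, 6, c(5, 8), frequency_map = fm, seed = 17)
  for (p in les$patients) {
    expect_gt(sum(p$lesion == 1L & network_mask(w, 1) == 1L), 0)
  }
  expect_error(generate_lesions(w, 2, c(5, 8), frequency_map = -fm),
               "nonnegative")
})

test_that("tract bundles are valid voxel paths", {
  w <- fx_world()
  ts <- fx_tracts()
  expect_length(ts$subjects, 4)
  for (subj in ts$subjects) {
    expect_length(subj, 6)
    for (path in subj) {
      expect_true(all(path >= 1))
      expect_true(all(t(path) <= w$spec$dims))
      if (nrow(path) > 1) {
        expect_true(all(abs(diff(path)) <= 1))
      }
    }
  }
})

test_that("disconnectome is the per-subject intersection frequency", {
  dims <- c(8L, 8L, 8L)
  lesion <- array(0L, dims); lesion[4, 4, 4] <- 1L
  # hand-built tract set: subject 1 has a bundle through the lesion,
  # subject 2 does not
  path_hit <- rbind(c(2, 4, 4), c(3, 4, 4), c(4, 4, 4), c(5, 4, 4))
  path_miss <- rbind(c(1, 1, 1), c(2, 2, 2))
  tracts <- structure(list(subjects = list(list(path_hit, path_miss),
                                           list(path_miss))),
                      class = "tract_set")
  dc <- compute_disconnectome(lesion, tracts, lesion_value_one = FALSE)
  expect_equal(dc[3, 4, 4], 0.5)   # on the hitting bundle, 1 of 2 subjects
  expect_equal(dc[1, 1, 1], 0)     # non-intersecting bundle contributes 0
  dc1 <- compute_disconnectome(lesion, tracts)
  expect_equal(dc1[4, 4, 4], 1)    # lesion core convention
  expect_true(all(dc >= 0 & dc <= 1))
  expect_error(compute_disconnectome(lesion,
                                     structure(list(subjects = list()),
                                               class = "tract_set")),
               "empty tract set")
})
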