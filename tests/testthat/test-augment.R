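test_that("intensity jitter scales whole slices and spares labels", {
  sc <- toy_scan(shape = c(8L, 8L, 3L), n_modalities = 2L, seed = 21)
  sc$volume <- sc$volume + 10  # keep voxels away from zero for ratio checks
  set.seed(1)
  same <- intensity_jitter(sc$volume, range = c(1, 1))
  expect_identical(same, sc$volume)
  set.seed(2)
  out <- intensity_jitter(sc$volume, range = c(0.8, 1.2))
  for (m in 1:2) {
    for (z in 1:3) {
      ratio <- out[, , z, m] / sc$volume[, , z, m]
      expect_lt(diff(range(ratio)), 1e-12)  # constant across the slice
      expect_gte(ratio[1], 0.8)
      expect_lte(ratio[1], 1.2)
    }
  }
  # the factors reproduce the seeded uniform stream (z fast, modality slow)
  set.seed(2)
  fac <- matrix(runif(3 * 2, 0.8, 1.2), 3, 2)
  for (m in 1:2) {
    for (z in 1:3) {
      expect_equal(out[1, 1, z, m] / sc$volume[1, 1, z, m], fac[z, m],
                   tolerance = 1e-12)
    }
  }
})

test_that("quarter-turn rotations compose to the identity", {
  set.seed(3)
  m <- matrix(rnorm(6 * 6), 6, 6)
  r <- brainseg:::rot90_mat
  expect_identical(r(m, 0), m)
  expect_equal(r(r(r(r(m, 1), 1), 1), 1), m)
  expect_equal(r(m, 2), m[6:1, 6:1])
  mr <- matrix(rnorm(4 * 6), 4, 6)  # non-square swaps extents
  expect_equal(dim(r(mr, 1)), c(6, 4))
  expect_equal(r(r(mr, 1), 3), mr)
})

test_that("identity configuration leaves both volumes untouched", {
  sc <- toy_scan(shape = c(8L, 8L, 3L), seed = 22)
  cfg <- augment_config(rotation_choices = 0, rescale_range = c(1, 1),
                        flip_prob = 0, crop_size = c(8L, 8L))
  set.seed(5)
  out <- geometric_augment(sc$volume, sc$labels, cfg)
  expect_equal(out$volume, sc$volume)
  expect_identical(out$labels, sc$labels)
})

test_that("rotations and flips preserve per-class voxel counts", {
  sc <- toy_scan(shape = c(8L, 8L, 3L), n_classes = 3L, seed = 23)
  cfg <- augment_config(rescale_range = c(1, 1), crop_size = c(8L, 8L))
  for (i in 1:5) {
    set.seed(30 + i)
    out <- geometric_augment(sc$volume, sc$labels, cfg)
    expect_identical(table(factor(out$labels, 0:2)),
                     table(factor(sc$labels, 0:2)))
    # intensities are permuted, not altered
    expect_equal(sort(as.vector(out$volume)), sort(as.vector(sc$volume)))
  }
})

test_that("images and labels receive identical geometric parameters", {
  # encode the in-plane coordinate grid as both image and label content;
  # with rescale disabled every transform is an exact index permutation,
  # so the two channels must stay equal voxel-for-voxel
  shape <- c(8L, 8L, 2L)
  grid <- array(rep(outer(seq_len(8), seq_len(8) * 100, `+`), 2), dim = shape)
  vol <- array(grid, dim = c(shape, 1))
  lab <- array(as.integer(grid), dim = shape)
  cfg <- augment_config(rescale_range = c(1, 1), crop_size = c(8L, 8L))
  for (i in 1:5) {
    set.seed(40 + i)
    out <- geometric_augment(vol, lab, cfg)
    expect_equal(as.integer(out$volume[, , , 1]), as.vector(out$labels))
  }
})

test_that("labels stay in the class set after rescaling augmentation", {
  sc <- toy_scan(shape = c(16L, 16L, 3L), n_classes = 3L, seed = 24)
  cfg <- augment_config(crop_size = c(8L, 8L))
  for (i in 1:5) {
    set.seed(50 + i)
    out <- geometric_augment(sc$volume, sc$labels, cfg)
    expect_true(all(out$labels %in% 0:2))
    expect_equal(dim(out$labels), c(8, 8, 3))
    expect_equal(dim(out$volume), c(8, 8, 3, 2))
  }
})

test_that("crops contain the lesion bounding box when it fits", {
  sc <- toy_scan(shape = c(16L, 16L, 3L), seed = 25)
  cfg <- augment_config(rotation_choices = 0, rescale_range = c(1, 1),
                        flip_prob = 0, crop_size = c(8L, 8L))
  n_lesion <- sum(sc$labels > 0)
  for (i in 1:10) {
    set.seed(60 + i)
    out <- geometric_augment(sc$volume, sc$labels, cfg)
    expect_equal(sum(out$labels > 0), n_lesion)  # whole ROI retained
  }
})

test_that("maybe_augment applies with the configured probability", {
  sc <- toy_scan(shape = c(8L, 8L, 2L), seed = 26)
  cfg0 <- augment_config(apply_prob = 0, crop_size = c(8L, 8L))
  cfg1 <- augment_config(apply_prob = 1, crop_size = c(8L, 8L),
                         rotation_choices = 0, rescale_range = c(1, 1),
                         flip_prob = 0)
  set.seed(70)
  expect_false(maybe_augment(sc$volume, sc$labels, cfg0)$augmented)
  expect_true(maybe_augment(sc$volume, sc$labels, cfg1)$augmented)
  cfg5 <- augment_config(apply_prob = 0.5, crop_size = c(8L, 8L))
  set.seed(71)
  hits <- vapply(seq_len(10000), function(i) {
    maybe_augment(sc$volume, sc$labels, cfg5)$augmented
  }, logical(1))
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
})

test_that("a fixed seed reproduces augmented samples bit-exactly", {
  sc <- toy_scan(shape = c(16L, 16L, 3L), seed = 27)
  cfg <- augment_config(apply_prob = 1, crop_size = c(8L, 8L))
  set.seed(80)
  a <- maybe_augment(sc$volume, sc$labels, cfg)
  set.seed(80)
  b <- maybe_augment(sc$volume, sc$labels, cfg)
  expect_identical(a, b)
})
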