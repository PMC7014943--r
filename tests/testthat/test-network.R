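test_that("backbone layer count is 17 regardless of width", {
  for (cfg in list(seg_config(),
                   desk_config(),
                   seg_config(n_modalities = 6, n_classes = 2,
                              block_channels = c(8, 16, 32, 64),
                              refine_channels = 16))) {
    d <- describe_network(build_model(cfg, seed = 1))
    expect_equal(d$backbone_conv_count, 17L)
  }
})

test_that("parameter totals match an independent closed-form summation", {
  count_params <- function(M, ch, r, K) {
    backbone <- 27 * M * ch[1] + 27 * ch[1]^2 +
      sum(27 * ch[1:3] * ch[2:4]) + sum(4 * 27 * ch[2:4]^2)
    bn_backbone <- 2 * (2 * ch[1] + sum(5 * ch[2:4]))
    adaptive <- sum(ch) * r + 4 * 2 * r
    refine <- 3 * (2 * (r^2 + r) + 27 * r^2 + 2 * r)
    head <- r * K + K
    backbone + bn_backbone + adaptive + refine + head
  }
  d_def <- describe_network(build_model(seg_config(), seed = 1))
  expect_equal(d_def$total_parameters,
               count_params(4, c(32, 64, 128, 256), 128, 5))
  d_tiny <- describe_network(build_model(
    seg_config(n_modalities = 6, n_classes = 2,
               block_channels = c(8, 16, 32, 64), refine_channels = 16),
    seed = 1))
  expect_equal(d_tiny$total_parameters, count_params(6, c(8, 16, 32, 64), 16, 2))
  # the per-layer table is consistent with the realized parameter arrays
  expect_equal(d_def$total_parameters,
               sum(lengths(build_model(seg_config(), seed = 2)$params)))
})

test_that("default model parameter count rounds to 12 million", {
  d <- describe_network(build_model(seg_config(), seed = 1))
  expect_equal(round(d$total_parameters / 1e6), 12)
})

test_that("feature maps scale by 1, 1/2, 1/4, 1/8 in plane only", {
  fs <- feature_shapes(seg_config(), c(128, 128, 12))
  expect_equal(fs$x, c(128, 64, 32, 16))
  expect_equal(fs$y, c(128, 64, 32, 16))
  expect_equal(fs$z, rep(12, 4))
  expect_equal(fs$channels, c(32, 64, 128, 256))
  expect_equal(unlist(fs[1, c("x", "y", "z")], use.names = FALSE),
               c(128, 128, 12))
  fsd <- feature_shapes(seg_config(depth_downsample = TRUE), c(128, 128, 16))
  expect_equal(fsd$z, c(16, 8, 4, 2))
})

test_that("forward returns softmax at input resolution", {
  m <- build_model(micro_config(), seed = 5)
  x <- array(rnorm(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(16, 16, 3, 3))
  expect_lt(max(abs(rowSums(matrix(p, ncol = 3)) - 1)), 1e-5)
  # deterministic in evaluation mode
  expect_identical(p, predict(m, x, type = "prob"))
  # depth-preserving strides work on a 2-slice input
  x2 <- array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
  expect_equal(dim(predict(m, x2, type = "prob")), c(8, 8, 2, 3))
})

test_that("indivisible in-plane extents are rejected with the multiple", {
  m <- build_model(micro_config(), seed = 1)
  x <- array(rnorm(12 * 12 * 2 * 2), dim = c(12, 12, 2, 2))
  expect_error(predict(m, x), "multiples of 8")
  md <- build_model(seg_config(n_modalities = 2, n_classes = 3,
                               block_channels = c(4, 6, 8, 10),
                               refine_channels = 5, depth_downsample = TRUE),
                    seed = 1)
  xd <- array(rnorm(8 * 8 * 6 * 2), dim = c(8, 8, 6, 2))
  expect_error(predict(md, xd), "multiple of 8")
})

test_that("x2 up-sampling reproduces the bilinear interpolation oracle", {
  up <- brainseg:::upsample3d_fwd
  xin <- matrix(c(1, 2, 3, 4), nrow = 1)  # 2x2x1 ramp, one channel
  out <- up(xin, 2L, 2L, 1L, 2L, 2L, 1L, FALSE)
  # oracle: input position of output voxel o (0-based) is (o + 0.5)/2 - 0.5,
  # clamped at the borders, linearly interpolated between floor and ceil
  wts <- list(c(1, 0), c(0.75, 0.25), c(0.25, 0.75), c(1, 0))
  i0s <- c(1, 1, 1, 2)
  xm <- matrix(c(1, 2, 3, 4), 2, 2)
  expected <- matrix(0, 4, 4)
  for (ox in 1:4) {
    for (oy in 1:4) {
      i0 <- i0s[ox]; wx <- wts[[ox]]
      j0 <- i0s[oy]; wy <- wts[[oy]]
      i1 <- min(i0 + 1, 2); j1 <- min(j0 + 1, 2)
      expected[ox, oy] <- wx[1] * wy[1] * xm[i0, j0] +
        wx[2] * wy[1] * xm[i1, j0] + wx[1] * wy[2] * xm[i0, j1] +
        wx[2] * wy[2] * xm[i1, j1]
    }
  }
  expect_equal(matrix(out, 4, 4), expected, tolerance = 1e-12)
  # nearest mode duplicates voxels
  near <- up(xin, 2L, 2L, 1L, 2L, 2L, 1L, TRUE)
  expect_equal(matrix(near, 4, 4), xm[rep(1:2, each = 2), rep(1:2, each = 2)])
})

test_that("up-sampling adjoint satisfies the inner-product identity", {
  set.seed(8)
  fwd <- brainseg:::upsample3d_fwd
  adj <- brainseg:::upsample3d_adj
  for (nearest in c(FALSE, TRUE)) {
    x <- matrix(rnorm(3 * 4 * 3 * 2), nrow = 3)
    y <- matrix(rnorm(3 * 8 * 6 * 2), nrow = 3)
    ax <- fwd(x, 4L, 3L, 2L, 2L, 2L, 1L, nearest)
    aty <- adj(y, 4L, 3L, 2L, 2L, 2L, 1L, nearest)
    expect_equal(sum(ax * y), sum(x * aty), tolerance = 1e-10)
  }
})

test_that("refine units fuse branches and preserve the fine shape", {
  set.seed(10)
  r <- 4L
  fine_dims <- c(8L, 8L, 2L)
  coarse_dims <- c(4L, 4L, 2L)
  fine <- matrix(rnorm(r * prod(fine_dims)), nrow = r)
  coarse <- matrix(rnorm(r * prod(coarse_dims)), nrow = r)
  params <- list(fine.W = diag(r), fine.bias = rep(0, r),
                 coarse.W = diag(r), coarse.bias = rep(0, r),
                 post.W = matrix(rnorm(r * r * 27, sd = 0.1), nrow = r),
                 post.g = rep(1, r), post.b = rep(0, r),
                 post.rm = rep(0, r), post.rv = rep(1, r))
  out <- brainseg:::refine_unit(fine, fine_dims, coarse, coarse_dims, params)
  expect_equal(dim(out), c(r, prod(fine_dims)))
  # additive identity: a zero coarse branch leaves the fine branch alone
  out0 <- brainseg:::refine_unit(fine, fine_dims, coarse * 0, coarse_dims,
                                 params)
  z <- brainseg:::conv3d_fwd(fine, 8L, 8L, 2L, params$post.W, 3L, 1L, 1L, 1L)
  zn <- (z - 0) / sqrt(1 + 1e-5)
  expect_equal(out0, zn * (zn > 0), tolerance = 1e-12)
  expect_error(
    brainseg:::refine_unit(fine, fine_dims, coarse[1:2, ], coarse_dims, params),
    "equal channel counts")
})

test_that("analytic gradients match finite differences through the loss", {
  set.seed(42)
  ns <- asNamespace("brainseg")
  m <- build_model(micro_config(), seed = 42)
  dims <- c(8L, 8L, 3L)
  B <- 2L
  x <- matrix(rnorm(2 * prod(dims) * B), nrow = 2)
  tg <- sample(0:2, prod(dims) * B, replace = TRUE)
  gamma <- 2
  loss_of <- function(model) {
    fw <- ns$nn_forward(model, x, dims, B = B, training = TRUE, keep = FALSE)
    p <- ns$softmax_cols(fw$logits)
    idx <- (seq_along(tg) - 1L) * nrow(p) + tg + 1L
    pt <- pmin(pmax(p[idx], 1e-7), 1)
    mean((1 - pt)^gamma * (-log(pt)))
  }
  fw <- ns$nn_forward(m, x, dims, B = B, training = TRUE, keep = TRUE)
  G <- ns$nn_backward(m, fw,
                      ns$focal_grad_logits(ns$softmax_cols(fw$logits), tg, gamma))
  h <- 1e-5
  set.seed(7)
  check_names <- c("b1c1.W", "b2d.W", "b3r1c1.W", "b4r2c2.g", "adapt2.W",
                   "ref2_coarse.W", "ref1_post.W", "ref1_fine.bias",
                   "head.W", "head.bias", "b2r1c2.b")
  for (nm in check_names) {
    for (ii in sample(seq_along(m$params[[nm]]), 2)) {
      m2 <- m; m2$params[[nm]][ii] <- m2$params[[nm]][ii] + h
      m3 <- m; m3$params[[nm]][ii] <- m3$params[[nm]][ii] - h
      fd <- (loss_of(m2) - loss_of(m3)) / (2 * h)
      an <- G[[nm]][ii]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
    }
  }
})

test_that("parameter count is independent of the input extent", {
  m <- build_model(micro_config(), seed = 3)
  n_par <- sum(lengths(m$params))
  for (shape in list(c(8, 8, 2), c(16, 16, 2), c(16, 32, 4))) {
    x <- array(rnorm(prod(shape) * 2), dim = c(shape, 2))
    p <- predict(m, x, type = "prob")
    expect_equal(dim(p), c(shape, 3))
  }
  expect_equal(sum(lengths(m$params)), n_par)
})
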