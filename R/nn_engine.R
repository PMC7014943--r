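# Forward/backward engine for the segmentation network.
#
# Activations are C x (N*B) matrices: C channels, N = prod(dims) voxels per
# sample in [x, y, z] column-major order, B samples stored as contiguous
# column blocks. Convolutions and up-sampling act per sample (geometry-aware
# kernels in src/nn_ops.cpp); batch normalization pools statistics over the
# whole batch, matching dense-segmentation practice where every voxel is a
# sample.

# (modalities last) 4D array -> M x N matrix and back
vol_to_mat <- function(a) {
  d <- dim(a)
  t(matrix(a, nrow = prod(d[1:3]), ncol = d[4]))
}

mat_to_vol <- function(m, dims) {
  array(t(m), dim = c(dims, nrow(m)))
}

out_dims <- function(dims, k, stride) {
  if (k == 1L) return(as.integer(dims))
  as.integer((dims - 1) %/% stride + 1L)
}

conv_b <- function(x, dims, B, W, k, stride) {
  if (k == 1L) return(W %*% x)
  N <- prod(dims)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * N + 1L):(b * N)
    out[[b]] <- conv3d_fwd(x[, cols, drop = FALSE],
                           dims[1], dims[2], dims[3],
                           W, k, stride[1], stride[2], stride[3])
  }
  if (B == 1L) out[[1L]] else do.call(cbind, out)
}

conv_b_bwd <- function(x, dims, B, W, k, stride, dy) {
  if (k == 1L) return(list(dW = dy %*% t(x), dx = t(W) %*% dy))
  N <- prod(dims)
  No <- ncol(dy) / B
  dW <- 0
  dxs <- vector("list", B)
  for (b in seq_len(B)) {
    r <- conv3d_bwd(x[, ((b - 1L) * N + 1L):(b * N), drop = FALSE],
                    dims[1], dims[2], dims[3],
                    W, k, stride[1], stride[2], stride[3],
                    dy[, ((b - 1L) * No + 1L):(b * No), drop = FALSE])
    dW <- dW + r$dW
    dxs[[b]] <- r$dx
  }
  list(dW = dW, dx = if (B == 1L) dxs[[1L]] else do.call(cbind, dxs))
}

upsample_b <- function(x, dims, B, fct, nearest) {
  N <- prod(dims)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    out[[b]] <- upsample3d_fwd(x[, ((b - 1L) * N + 1L):(b * N), drop = FALSE],
                               dims[1], dims[2], dims[3],
                               fct[1], fct[2], fct[3], nearest)
  }
  if (B == 1L) out[[1L]] else do.call(cbind, out)
}

upsample_b_adj <- function(dy, dims, B, fct, nearest) {
  No <- ncol(dy) / B
  out <- vector("list", B)
  for (b in seq_len(B)) {
    out[[b]] <- upsample3d_adj(dy[, ((b - 1L) * No + 1L):(b * No), drop = FALSE],
                               dims[1], dims[2], dims[3],
                               fct[1], fct[2], fct[3], nearest)
  }
  if (B == 1L) out[[1L]] else do.call(cbind, out)
}

# Full forward pass. `x` is an M x (N*B) matrix; returns logits (K x N*B),
# updated BN buffers, and (when keep = TRUE) the caches needed by
# nn_backward.
nn_forward <- function(model, x, dims, B = 1L, training = FALSE,
                       keep = training) {
  cfg <- model$config
  P <- model$params
  BUF <- model$buffers
  CA <- if (keep) new.env(parent = emptyenv()) else NULL
  stride2 <- if (cfg$depth_downsample) c(2L, 2L, 2L) else c(2L, 2L, 1L)
  bn_mom <- 0.9
  bn_eps <- 1e-5
  nearest <- cfg$upsample_mode == "nearest"

  cbr <- function(nm, x, dims, stride = c(1L, 1L, 1L), k = 3L, relu = TRUE) {
    W <- P[[paste0(nm, ".W")]]
    z <- conv_b(x, dims, B, W, k, stride)
    odims <- out_dims(dims, k, stride)
    g <- P[[paste0(nm, ".g")]]
    be <- P[[paste0(nm, ".b")]]
    if (training) {
      m <- rowMeans(z)
      xc <- z - m
      v <- rowMeans(xc * xc)
      inv <- 1 / sqrt(v + bn_eps)
      xhat <- xc * inv
      BUF[[paste0(nm, ".rm")]] <<- bn_mom * BUF[[paste0(nm, ".rm")]] + (1 - bn_mom) * m
      BUF[[paste0(nm, ".rv")]] <<- bn_mom * BUF[[paste0(nm, ".rv")]] + (1 - bn_mom) * v
    } else {
      inv <- 1 / sqrt(BUF[[paste0(nm, ".rv")]] + bn_eps)
      xhat <- (z - BUF[[paste0(nm, ".rm")]]) * inv
    }
    y <- xhat * g + be
    if (relu) y <- y * (y > 0)
    if (keep) {
      CA[[nm]] <- list(x = x, dims = dims, stride = stride, k = k,
                       xhat = xhat, inv = inv, y = y, relu = relu)
    }
    list(y = y, dims = odims)
  }

  lin <- function(nm, x) {
    y <- P[[paste0(nm, ".W")]] %*% x + P[[paste0(nm, ".bias")]]
    if (keep) CA[[nm]] <- list(x = x)
    y
  }

  resblock <- function(nm, x, dims) {
    a <- cbr(paste0(nm, "c1"), x, dims)
    b <- cbr(paste0(nm, "c2"), a$y, dims, relu = FALSE)
    z <- b$y + x
    y <- z * (z > 0)
    if (keep) CA[[paste0(nm, ".add")]] <- list(y = y)
    list(y = y, dims = dims)
  }

  h <- cbr("b1c1", x, dims)
  h <- cbr("b1c2", h$y, h$dims)
  Fi <- list(h$y)
  Di <- list(h$dims)
  cur <- h
  for (b in 2:4) {
    cur <- cbr(paste0("b", b, "d"), cur$y, Di[[b - 1L]], stride = stride2)
    for (j in seq_len(cfg$resblocks_per_block[b])) {
      cur <- resblock(paste0("b", b, "r", j), cur$y, cur$dims)
    }
    Fi[[b]] <- cur$y
    Di[[b]] <- cur$dims
  }

  A <- vector("list", 4L)
  for (i in 1:4) A[[i]] <- cbr(paste0("adapt", i), Fi[[i]], Di[[i]], k = 1L)$y

  R <- A[[4L]]
  Rd <- Di[[4L]]
  for (i in 3:1) {
    u <- lin(paste0("ref", i, "_fine"), A[[i]])
    v0 <- lin(paste0("ref", i, "_coarse"), R)
    fct <- as.integer(Di[[i]] / Rd)
    v <- upsample_b(v0, Rd, B, fct, nearest)
    pr <- cbr(paste0("ref", i, "_post"), u + v, Di[[i]])
    if (keep) CA[[paste0("ref", i)]] <- list(Rd = Rd, fct = fct)
    R <- pr$y
    Rd <- Di[[i]]
  }
  logits <- P[["head.W"]] %*% R + P[["head.bias"]]
  if (keep) CA[["head"]] <- list(x = R)
  list(logits = logits, refine_channels = nrow(R), dims = dims, B = B,
       cache = CA, buffers = BUF, block_dims = Di)
}

# Backward pass; returns a named list of gradients aligned with
# model$params. `fw` is the value of nn_forward(..., keep = TRUE).
nn_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  P <- model$params
  CA <- fw$cache
  B <- fw$B
  G <- new.env(parent = emptyenv())
  addg <- function(nm, val) {
    G[[nm]] <- if (exists(nm, envir = G, inherits = FALSE)) G[[nm]] + val else val
  }

  cbr_bwd <- function(nm, dy) {
    cc <- CA[[nm]]
    if (cc$relu) dy <- dy * (cc$y > 0)
    g <- P[[paste0(nm, ".g")]]
    addg(paste0(nm, ".g"), rowSums(dy * cc$xhat))
    addg(paste0(nm, ".b"), rowSums(dy))
    dxhat <- dy * g
    n <- ncol(dxhat)
    dz <- (cc$inv / n) *
      (n * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
    bw <- conv_b_bwd(cc$x, cc$dims, B, P[[paste0(nm, ".W")]],
                     cc$k, cc$stride, dz)
    addg(paste0(nm, ".W"), bw$dW)
    bw$dx
  }

  lin_bwd <- function(nm, dy) {
    cc <- CA[[nm]]
    addg(paste0(nm, ".W"), dy %*% t(cc$x))
    addg(paste0(nm, ".bias"), rowSums(dy))
    t(P[[paste0(nm, ".W")]]) %*% dy
  }

  resblock_bwd <- function(nm, dy) {
    dz <- dy * (CA[[paste0(nm, ".add")]]$y > 0)
    da <- cbr_bwd(paste0(nm, "c2"), dz)
    dx <- cbr_bwd(paste0(nm, "c1"), da)
    dx + dz
  }

  hc <- CA[["head"]]
  addg("head.W", dlogits %*% t(hc$x))
  addg("head.bias", rowSums(dlogits))
  dR <- t(P[["head.W"]]) %*% dlogits

  dA <- vector("list", 4L)
  for (i in 1:3) {
    ds <- cbr_bwd(paste0("ref", i, "_post"), dR)
    rc <- CA[[paste0("ref", i)]]
    dA[[i]] <- lin_bwd(paste0("ref", i, "_fine"), ds)
    dv0 <- upsample_b_adj(ds, rc$Rd, B, rc$fct,
                          cfg$upsample_mode == "nearest")
    dR <- lin_bwd(paste0("ref", i, "_coarse"), dv0)
  }
  dA[[4L]] <- dR

  dF <- vector("list", 4L)
  for (i in 1:4) dF[[i]] <- cbr_bwd(paste0("adapt", i), dA[[i]])

  dh <- dF[[4L]]
  for (b in 4:2) {
    for (j in rev(seq_len(cfg$resblocks_per_block[b]))) {
      dh <- resblock_bwd(paste0("b", b, "r", j), dh)
    }
    dh <- cbr_bwd(paste0("b", b, "d"), dh)
    dh <- dh + dF[[b - 1L]]
  }
  dh <- cbr_bwd("b1c2", dh)
  cbr_bwd("b1c1", dh)
  as.list(G)
}

# Column-wise softmax of a K x N logit matrix.
softmax_cols <- function(z) {
  K <- nrow(z)
  m <- z[1L, ]
  if (K > 1L) for (k in 2:K) m <- pmax(m, z[k, ])
  e <- exp(z - rep(m, each = K))
  e / rep(colSums(e), each = K)
}

# Standalone refine unit: fuse fine features with x2-up-sampled coarse
# features. Both inputs are C x N matrices with refine-width channels;
# `params` supplies the branch 1x1x1 convolutions (fine.W/fine.bias,
# coarse.W/coarse.bias) and the post-sum 3x3x3 convolution (post.W, post.g,
# post.b, post.rm, post.rv; batch-norm in evaluation mode). Used by the full
# network through nn_forward; exposed for direct inspection/testing.
refine_unit <- function(fine, fine_dims, coarse, coarse_dims, params,
                        mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (nrow(fine) != nrow(coarse)) {
    stop("fine and coarse branches must have equal channel counts",
         call. = FALSE)
  }
  fct <- as.integer(fine_dims / coarse_dims)
  u <- params$fine.W %*% fine + params$fine.bias
  v <- params$coarse.W %*% coarse + params$coarse.bias
  v <- upsample3d_fwd(v, coarse_dims[1], coarse_dims[2], coarse_dims[3],
                      fct[1], fct[2], fct[3], mode == "nearest")
  s <- u + v
  z <- conv3d_fwd(s, fine_dims[1], fine_dims[2], fine_dims[3],
                  params$post.W, 3L, 1L, 1L, 1L)
  xhat <- (z - params$post.rm) / sqrt(params$post.rv + 1e-5)
  y <- xhat * params$post.g + params$post.b
  y * (y > 0)
}
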