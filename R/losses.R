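#' Focal loss for dense voxel classification
#'
#' The focal loss re-weights the cross-entropy of each voxel by
#' `(1 - p_t)^gamma`, where `p_t` is the probability the model assigns to the
#' voxel's true class: well-classified ("easy") voxels, which dominate dense
#' 3D segmentation, are smoothly down-weighted so training concentrates on
#' hard voxels. With `gamma = 0` it reduces exactly to mean cross-entropy.
#' The multi-class form used here applies the binary definition per voxel to
#' the softmax probability of the true class and averages over all voxels.
#'
#' `p_t` is clamped below at `1e-7` before taking logarithms.
#'
#' @param probabilities Class probabilities: a `K x N` matrix (rows =
#'   classes) or a 4D array `[x, y, z, K]`. Each voxel's probabilities must
#'   sum to 1 within `1e-4`.
#' @param targets True class per voxel as 0-based labels (`0 .. K-1`),
#'   matching the probability rows; a vector of length `N` or a 3D array.
#' @param gamma Focusing parameter, >= 0. Default 2, the canonical choice.
#' @param class_weights Optional length-`K` per-class multipliers (default
#'   uniform).
#' @return Mean loss over all voxels (scalar).
#' @examples
#' p <- matrix(c(0.9, 0.1), nrow = 2)
#' focal_loss(p, targets = 0, gamma = 0)   # -log(0.9)
#' focal_loss(p, targets = 0, gamma = 2)   # 0.1^2 * -log(0.9)
#' @export
focal_loss <- function(probabilities, targets, gamma = 2,
                       class_weights = NULL) {
  pt <- loss_inputs(probabilities, targets, gamma, class_weights)
  mean(pt$w * (1 - pt$pt)^gamma * (-log(pt$pt)))
}

#' Mean cross-entropy loss
#'
#' Identical (bit-for-bit) to [focal_loss()] with `gamma = 0`.
#'
#' @inheritParams focal_loss
#' @return Mean negative log-probability of the true class.
#' @export
cross_entropy <- function(probabilities, targets, class_weights = NULL) {
  focal_loss(probabilities, targets, gamma = 0, class_weights = class_weights)
}

#' Gradient of the focal loss with respect to the probabilities
#'
#' The loss depends on a voxel's probability vector only through the true
#' class entry, so the gradient is nonzero only there:
#' `d/dp_t [-(1-p_t)^g log p_t] = g (1-p_t)^(g-1) log(p_t) - (1-p_t)^g / p_t`,
#' divided by the number of voxels (mean reduction).
#'
#' @inheritParams focal_loss
#' @return An object shaped like `probabilities` holding the gradient.
#' @export
focal_loss_grad <- function(probabilities, targets, gamma = 2,
                            class_weights = NULL) {
  pt <- loss_inputs(probabilities, targets, gamma, class_weights)
  p <- pt$pt
  g <- if (gamma == 0) -1 / p else {
    gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p
  }
  out <- array(0, dim = dim(pt$p))
  out[pt$idx] <- pt$w * g / length(p)
  if (pt$was_array) array(t(out), dim = pt$orig_dim) else out
}

# Shared validation/shaping for the loss functions. Accepts K x N matrices
# (class rows) or [x,y,z,K] arrays; returns clamped true-class probabilities.
loss_inputs <- function(probabilities, targets, gamma, class_weights,
                        eps = 1e-7) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  was_array <- is.array(probabilities) && length(dim(probabilities)) == 4L
  orig_dim <- dim(probabilities)
  p <- if (was_array) {
    t(matrix(probabilities, nrow = prod(orig_dim[1:3]), ncol = orig_dim[4]))
  } else {
    as.matrix(probabilities)
  }
  K <- nrow(p)
  n <- ncol(p)
  tg <- as.integer(as.vector(targets))
  if (length(tg) != n) {
    stop("targets length (", length(tg), ") does not match voxel count (",
         n, ")", call. = FALSE)
  }
  if (any(tg < 0L | tg >= K)) {
    stop("targets must be 0-based class labels in 0..", K - 1L, call. = FALSE)
  }
  if (any(p < -1e-8) || any(p > 1 + 1e-8)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  sums <- colSums(p)
  if (any(abs(sums - 1) > 1e-4)) {
    stop("per-voxel probabilities must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  idx <- (seq_len(n) - 1L) * K + tg + 1L
  ptv <- pmin(pmax(p[idx], eps), 1)
  w <- if (is.null(class_weights)) 1 else {
    if (length(class_weights) != K) {
      stop("class_weights must have length ", K, call. = FALSE)
    }
    class_weights[tg + 1L]
  }
  list(p = p, pt = ptv, idx = idx, w = w,
       was_array = was_array, orig_dim = orig_dim)
}

# Gradient of the mean focal loss with respect to the *logits*, used by the
# trainer: dL/dz_k = c * (delta_{k,t} - p_k) with
# c = (dL/dp_t) * p_t / N. For gamma = 0 this is the usual (p - onehot)/N.
focal_grad_logits <- function(p, targets0, gamma) {
  K <- nrow(p)
  n <- ncol(p)
  idx <- (seq_len(n) - 1L) * K + targets0 + 1L
  pt <- pmin(pmax(p[idx], 1e-7), 1 - 1e-12)
  dldpt <- if (gamma == 0) -1 / pt else {
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  }
  cf <- dldpt * pt / n
  dz <- -p * rep(cf, each = K)
  dz[idx] <- dz[idx] + cf
  dz
}
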