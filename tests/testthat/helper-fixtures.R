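# Shared fixtures: tiny configurations and toy volumes used across tests.

# A micro network small enough for finite-difference checks (seconds).
micro_config <- function(n_modalities = 2L, n_classes = 3L) {
  seg_config(n_modalities = n_modalities, n_classes = n_classes,
             block_channels = c(4L, 6L, 8L, 10L), refine_channels = 5L)
}

# Tiny multi-modal array + matching labels with a centred blob lesion.
toy_scan <- function(shape = c(16L, 16L, 4L), n_modalities = 2L,
                     n_classes = 2L, seed = 1L) {
  set.seed(seed)
  labels <- array(0L, dim = shape)
  cx <- shape[1] / 2; cy <- shape[2] / 2
  for (z in seq_len(shape[3])) {
    labels[(cx - 2):(cx + 2), (cy - 2):(cy + 2), z] <- 1L
  }
  if (n_classes > 2L) labels[cx, cy, ] <- 2L
  data <- array(rnorm(prod(shape) * n_modalities), dim = c(shape, n_modalities))
  for (m in seq_len(n_modalities)) {
    sl <- array(data[, , , m], dim = shape)
    data[, , , m] <- sl + 5 * (labels > 0) + 2 * m * (labels == 2L)
  }
  list(volume = data, labels = labels)
}

# Random binary mask pair on a small grid.
random_mask_pair <- function(n = 6L, p = 0.4) {
  list(p = array(runif(n^3) < p, dim = rep(n, 3)),
       t = array(runif(n^3) < p, dim = rep(n, 3)))
}

# Brute-force confusion-matrix counting, the independent oracle for metrics.
confusion_scores <- function(pred, truth) {
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  list(
    dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    sens = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    spec = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    prec = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}
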