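#' Data-augmentation configuration
#'
#' Augmentation has two parts, applied in this order. (1) Slice-level
#' intensity jitter: every in-plane slice of every modality is multiplied by
#' an independent amplification factor drawn uniformly from
#' `intensity_range`. (2) Volume-level geometric augmentation, where the same
#' draw is applied identically to all slices (and, with nearest-neighbour
#' interpolation, to the labels): a rotation from `rotation_choices`, an
#' in-plane rescale by one factor from `rescale_range` (the result is
#' centre-cropped or zero-padded back to the original extent), a horizontal
#' then a vertical flip each with probability `flip_prob`, and finally an
#' ROI-constrained random crop to `crop_size` — the crop window must contain
#' the lesion's in-plane bounding box whenever a lesion is present.
#'
#' All randomness flows through R's global generator, so a fixed
#' `set.seed()` reproduces augmented batches exactly.
#'
#' @param intensity_range Range of the slice-level amplification factor.
#' @param rotation_choices Allowed in-plane rotations, degrees (multiples of
#'   90; applied exactly, without interpolation).
#' @param rescale_range Range of the in-plane rescale factor.
#' @param flip_prob Probability of each of the horizontal and vertical flips.
#' @param crop_size In-plane target size `c(x, y)` of the final crop.
#' @param apply_prob Fraction of samples that receive augmentation (the
#'   curriculum raises this across stages: 0, then 0.5, then 0.75).
#' @return An `augment_config` list.
#' @export
augment_config <- function(intensity_range = c(0.8, 1.2),
                           rotation_choices = c(0, 90, 180, 270),
                           rescale_range = c(0.5, 1.2),
                           flip_prob = 0.5,
                           crop_size = c(128L, 128L),
                           apply_prob = 0.5) {
  stopifnot(length(intensity_range) == 2L, all(intensity_range > 0),
            length(rescale_range) == 2L, all(rescale_range > 0),
            apply_prob >= 0, apply_prob <= 1,
            all(rotation_choices %% 90 == 0))
  structure(list(intensity_range = as.numeric(intensity_range),
                 rotation_choices = as.numeric(rotation_choices),
                 rescale_range = as.numeric(rescale_range),
                 flip_prob = flip_prob,
                 crop_size = as.integer(crop_size),
                 apply_prob = apply_prob),
            class = "augment_config")
}

#' Slice-level intensity jitter
#'
#' Multiplies each in-plane slice of each modality by an independent factor
#' drawn uniformly from `range`. Labels are never touched by intensity
#' augmentation.
#'
#' @param volume A `multimodal_volume` or 4D array `[x, y, z, modality]`.
#' @param range Amplification-factor range.
#' @return The jittered volume, same type as the input.
#' @export
intensity_jitter <- function(volume, range = c(0.8, 1.2)) {
  is_mm <- inherits(volume, "multimodal_volume")
  data <- if (is_mm) volume$data else volume
  d <- dim(data)
  factors <- matrix(runif(d[3] * d[4], range[1], range[2]), d[3], d[4])
  for (m in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      data[, , z, m] <- data[, , z, m] * factors[z, m]
    }
  }
  if (is_mm) {
    volume$data <- data
    volume
  } else {
    data
  }
}

# Exact 90-degree rotation of an in-plane slice (counter-clockwise in array
# coordinates); k in {0,1,2,3} quarter turns.
rot90_mat <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# In-plane rescale of one slice by factor s, then centre-crop/zero-pad back
# to the original extent. Bilinear for images, nearest for labels.
rescale_slice <- function(m, s, label = FALSE) {
  if (s == 1) return(m)
  d <- dim(m)
  nw <- max(1L, as.integer(round(d[1] * s)))
  nh <- max(1L, as.integer(round(d[2] * s)))
  r <- EBImage::resize(m, w = nw, h = nh,
                       filter = if (label) "none" else "bilinear")
  r <- matrix(as.numeric(r), nw, nh)
  out <- matrix(0, d[1], d[2])
  # centre alignment between old and new grids
  ox <- max(0L, (nw - d[1]) %/% 2L)
  oy <- max(0L, (nh - d[2]) %/% 2L)
  px <- max(0L, (d[1] - nw) %/% 2L)
  py <- max(0L, (d[2] - nh) %/% 2L)
  cw <- min(d[1], nw)
  ch <- min(d[2], nh)
  out[px + seq_len(cw), py + seq_len(ch)] <-
    r[ox + seq_len(cw), oy + seq_len(ch)]
  out
}

# In-plane lesion bounding box over a label slab; NULL when no lesion.
lesion_bbox <- function(labels) {
  pos <- which(labels > 0L, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(NULL)
  list(x = range(pos[, 1L]), y = range(pos[, 2L]))
}

# Sample a crop origin (1-based) for a window of `size` inside `extent` that
# contains `bb_range` (or centres on it, with a warning, if it cannot fit).
crop_origin <- function(extent, size, bb_range) {
  if (is.null(bb_range)) {
    return(sample.int(extent - size + 1L, 1L))
  }
  lo <- max(1L, bb_range[2L] - size + 1L)
  hi <- min(extent - size + 1L, bb_range[1L])
  if (lo > hi) {
    warning("lesion bounding box larger than crop window; centring on lesion",
            call. = FALSE)
    ctr <- as.integer(round(mean(bb_range)))
    return(min(max(1L, ctr - size %/% 2L), extent - size + 1L))
  }
  if (lo == hi) lo else sample(lo:hi, 1L)
}

#' Volume-level geometric augmentation
#'
#' Applies one shared draw of rotation, in-plane rescale, flips and
#' ROI-constrained crop identically to every slice of the image volume, and
#' with nearest-neighbour interpolation to the label volume, so image and
#' labels stay aligned. See [augment_config()] for the operation order.
#'
#' @param volume A `multimodal_volume` or 4D array.
#' @param labels Integer label array on the same grid.
#' @param config An [augment_config()].
#' @return A list with augmented `volume` (same type as input) and `labels`.
#' @export
geometric_augment <- function(volume, labels, config = augment_config()) {
  is_mm <- inherits(volume, "multimodal_volume")
  data <- if (is_mm) volume$data else volume
  d <- dim(data)
  stopifnot(identical(dim(labels), d[1:3]))
  rot_k <- sample(seq_along(config$rotation_choices), 1L)
  k90 <- as.integer(config$rotation_choices[rot_k] / 90) %% 4L
  s <- runif(1, config$rescale_range[1], config$rescale_range[2])
  flip_h <- runif(1) < config$flip_prob
  flip_v <- runif(1) < config$flip_prob

  slice_xform <- function(m, label) {
    m <- rot90_mat(m, k90)
    m <- rescale_slice(m, s, label = label)
    if (flip_h) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (flip_v) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m
  }

  # rotation may swap in-plane extents; probe with one slice
  probe <- rot90_mat(data[, , 1L, 1L], k90)
  nd <- c(dim(probe), d[3])
  out <- array(0, dim = c(nd, d[4]))
  for (m in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      out[, , z, m] <- slice_xform(data[, , z, m], label = FALSE)
    }
  }
  lab <- array(0L, dim = nd)
  for (z in seq_len(d[3])) {
    lab[, , z] <- as.integer(slice_xform(labels[, , z] * 1.0, label = TRUE))
  }

  cs <- pmin(config$crop_size, nd[1:2])
  if (any(cs < config$crop_size)) {
    stop("in-plane extent after rescale smaller than crop_size", call. = FALSE)
  }
  bb <- lesion_bbox(lab)
  x0 <- crop_origin(nd[1], cs[1], if (is.null(bb)) NULL else bb$x)
  y0 <- crop_origin(nd[2], cs[2], if (is.null(bb)) NULL else bb$y)
  out <- out[x0 + seq_len(cs[1]) - 1L, y0 + seq_len(cs[2]) - 1L, , , drop = FALSE]
  lab <- lab[x0 + seq_len(cs[1]) - 1L, y0 + seq_len(cs[2]) - 1L, , drop = FALSE]

  if (is_mm) {
    volume$data <- out
    list(volume = volume, labels = lab)
  } else {
    list(volume = out, labels = lab)
  }
}

#' Apply the full augmentation with a given probability
#'
#' With probability `config$apply_prob` the sample receives intensity jitter
#' followed by geometric augmentation; otherwise it passes through unchanged.
#' The curriculum stages raise `apply_prob` from 0 to 0.5 to 0.75.
#'
#' @inheritParams geometric_augment
#' @return A list with `volume`, `labels` and `augmented` (logical).
#' @export
maybe_augment <- function(volume, labels, config = augment_config()) {
  if (runif(1) < config$apply_prob) {
    v <- intensity_jitter(volume, config$intensity_range)
    g <- geometric_augment(v, labels, config)
    list(volume = g$volume, labels = g$labels, augmented = TRUE)
  } else {
    list(volume = volume, labels = labels, augmented = FALSE)
  }
}
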