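#' Plan non-overlapping windows along the slice axis
#'
#' Scans are windowed into fixed-depth sub-volumes along the slice axis:
#' `floor(D/d)` full non-overlapping windows at offsets `0, d, 2d, ...`,
#' plus — when `D` is not a multiple of `d` — one final remainder window
#' anchored at `D - d` so the whole scan is covered. The window count is
#' therefore `ceiling(D/d)`: a 155-slice scan with depth-12 windows yields
#' 13, a 20-slice scan with depth-7 windows yields 3 (offsets 0, 7, 13), and
#' a 155-slice scan with depth-31 windows yields 5.
#'
#' @param scan_depth Total number of slices `D`.
#' @param window_depth Slices per window `d` (must satisfy `d <= D`).
#' @return A `window_plan`: list with 0-based `offsets` (strictly
#'   increasing), `window_depth` and `scan_depth`.
#' @examples
#' plan_windows(155, 12)$offsets   # 13 windows
#' plan_windows(20, 7)$offsets     # 0 7 13
#' @export
plan_windows <- function(scan_depth, window_depth) {
  scan_depth <- as.integer(scan_depth)
  window_depth <- as.integer(window_depth)
  if (window_depth < 1L) stop("window_depth must be >= 1", call. = FALSE)
  if (window_depth > scan_depth) {
    stop("window_depth (", window_depth, ") exceeds scan depth (",
         scan_depth, ")", call. = FALSE)
  }
  offsets <- seq.int(0L, by = window_depth,
                     length.out = scan_depth %/% window_depth)
  if (scan_depth %% window_depth != 0L) {
    offsets <- c(offsets, scan_depth - window_depth)
  }
  structure(list(offsets = as.integer(offsets),
                 window_depth = window_depth,
                 scan_depth = scan_depth),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat("<window_plan> ", length(x$offsets), " windows of depth ",
      x$window_depth, " over ", x$scan_depth, " slices (0-based offsets: ",
      paste(x$offsets, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Extract fixed-size training patches from one scan
#'
#' One patch per planned window along the slice axis; the in-plane region of
#' each patch is chosen by the ROI-constrained random crop (the crop window
#' must contain the lesion's in-plane bounding box whenever the lesion
#' intersects the window's slab).
#'
#' @param volume A `multimodal_volume` or 4D array `[x, y, z, modality]`.
#' @param labels Integer label array on the same grid.
#' @param window_depth Slices per patch.
#' @param crop_size In-plane patch size `c(x, y)`.
#' @return A list of patches, each with `x` (4D array
#'   `[crop_x, crop_y, window_depth, M]`), `y` (aligned integer labels) and
#'   `offset` (0-based slice offset).
#' @export
extract_training_patches <- function(volume, labels, window_depth,
                                     crop_size = c(128L, 128L)) {
  data <- if (inherits(volume, "multimodal_volume")) volume$data else volume
  d <- dim(data)
  stopifnot(identical(dim(labels), d[1:3]))
  if (any(crop_size > d[1:2])) {
    stop("crop_size exceeds the in-plane extent", call. = FALSE)
  }
  plan <- plan_windows(d[3], window_depth)
  lapply(plan$offsets, function(off) {
    zr <- off + seq_len(window_depth)
    slab_lab <- labels[, , zr, drop = FALSE]
    bb <- lesion_bbox(slab_lab)
    x0 <- crop_origin(d[1], crop_size[1], if (is.null(bb)) NULL else bb$x)
    y0 <- crop_origin(d[2], crop_size[2], if (is.null(bb)) NULL else bb$y)
    xi <- x0 + seq_len(crop_size[1]) - 1L
    yi <- y0 + seq_len(crop_size[2]) - 1L
    list(x = data[xi, yi, zr, , drop = FALSE],
         y = slab_lab[xi, yi, , drop = FALSE],
         offset = off)
  })
}

#' Split a scan into full-plane inference sub-volumes
#'
#' Memory-bounded sliding-window inference: the scan is split along the slice
#' axis by [plan_windows()] with the full in-plane extent retained, each
#' sub-volume is predicted independently, and [stitch()] reassembles the
#' full-depth output.
#'
#' @param volume A `multimodal_volume` or 4D array.
#' @param subvolume_depth Slices per sub-volume.
#' @return A list with `subvolumes` (list of 4D arrays) and `plan`.
#' @export
split_inference <- function(volume, subvolume_depth) {
  data <- if (inherits(volume, "multimodal_volume")) volume$data else volume
  d <- dim(data)
  plan <- plan_windows(d[3], subvolume_depth)
  subs <- lapply(plan$offsets, function(off) {
    data[, , off + seq_len(subvolume_depth), , drop = FALSE]
  })
  list(subvolumes = subs, plan = plan)
}

#' Stitch per-sub-volume probabilities into a full-depth volume
#'
#' Non-overlapping slices are copied; slices covered by two windows (the
#' remainder window overlaps its neighbour when the scan depth is not a
#' multiple of the window depth) are averaged, then each voxel's class
#' probabilities are renormalized to sum to one.
#'
#' @param chunks List of probability arrays `[x, y, window_depth, K]`, one
#'   per window of `plan`, in plan order.
#' @param plan The `window_plan` used to split the scan.
#' @return A probability array `[x, y, scan_depth, K]`.
#' @export
stitch <- function(chunks, plan) {
  stopifnot(inherits(plan, "window_plan"),
            length(chunks) == length(plan$offsets))
  d <- dim(chunks[[1L]])
  stopifnot(length(d) == 4L, d[3] == plan$window_depth)
  out <- array(0, dim = c(d[1], d[2], plan$scan_depth, d[4]))
  count <- numeric(plan$scan_depth)
  for (i in seq_along(chunks)) {
    zr <- plan$offsets[i] + seq_len(plan$window_depth)
    out[, , zr, ] <- out[, , zr, , drop = FALSE] + chunks[[i]]
    count[zr] <- count[zr] + 1
  }
  if (any(count == 0)) stop("window plan does not cover every slice", call. = FALSE)
  for (z in which(count > 1)) out[, , z, ] <- out[, , z, , drop = FALSE] / count[z]
  # renormalize per voxel (guards against accumulated rounding)
  s <- rowSums(out, dims = 3L)
  for (k in seq_len(d[4])) out[, , , k] <- out[, , , k] / s
  out
}

#' Per-voxel class labels from a probability volume
#'
#' Takes the class of maximum probability at each voxel, with ties broken
#' toward the lower class index (background-favouring, deterministic). No
#' smoothing or post-processing is applied.
#'
#' @param probabilities Probability array `[x, y, z, K]` (class axis last).
#' @return Integer label array `[x, y, z]` with 0-based class labels.
#' @export
predict_labels <- function(probabilities) {
  d <- dim(probabilities)
  stopifnot(length(d) == 4L)
  p <- t(matrix(probabilities, nrow = prod(d[1:3]), ncol = d[4]))
  array(as.integer(argmax_cols(p)), dim = d[1:3])
}
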