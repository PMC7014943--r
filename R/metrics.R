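#' Overlap and voxel-classification metrics
#'
#' Standard segmentation scores over binary masks `P` (prediction) and `T`
#' (ground truth):
#' Dice `= 2|P∩T| / (|P|+|T|)` (identical to the F-measure), sensitivity
#' (true-positive rate) `= |P∩T| / |T|`, specificity (true-negative rate)
#' `= |P'∩T'| / |T'|`, and precision `= |P∩T| / |P|`.
#'
#' Degenerate cases follow common benchmark conventions: Dice is 1 when both
#' masks are empty and 0 when exactly one is; sensitivity, specificity and
#' precision return `NA` (undefined) when their denominator is empty, so they
#' can be excluded from aggregates.
#'
#' @param prediction,truth Binary masks: logical or 0/1 arrays of identical
#'   shape.
#' @return A score in `[0, 1]`, or `NA` where undefined.
#' @examples
#' p <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
#' t <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)
#' dice(p, t)         # 2*3/(4+6) = 0.6
#' sensitivity(p, t)  # 3/6 = 0.5
#' precision(p, t)    # 3/4
#' @name segmentation-metrics
NULL

check_pair <- function(prediction, truth) {
  if (!identical(dim(prediction), dim(truth)) ||
      length(prediction) != length(truth)) {
    stop("prediction and truth must have identical shapes", call. = FALSE)
  }
  p <- as.logical(prediction)
  t <- as.logical(truth)
  if (anyNA(p) || anyNA(t)) stop("masks must be binary 0/1", call. = FALSE)
  list(p = p, t = t)
}

#' @rdname segmentation-metrics
#' @export
dice <- function(prediction, truth) {
  m <- check_pair(prediction, truth)
  np <- sum(m$p)
  nt <- sum(m$t)
  if (np + nt == 0L) return(1)
  2 * sum(m$p & m$t) / (np + nt)
}

#' @rdname segmentation-metrics
#' @export
sensitivity <- function(prediction, truth) {
  m <- check_pair(prediction, truth)
  nt <- sum(m$t)
  if (nt == 0L) return(NA_real_)
  sum(m$p & m$t) / nt
}

#' @rdname segmentation-metrics
#' @export
specificity <- function(prediction, truth) {
  m <- check_pair(prediction, truth)
  nn <- sum(!m$t)
  if (nn == 0L) return(NA_real_)
  sum(!m$p & !m$t) / nn
}

#' @rdname segmentation-metrics
#' @export
precision <- function(prediction, truth) {
  m <- check_pair(prediction, truth)
  np <- sum(m$p)
  if (np == 0L) return(NA_real_)
  sum(m$p & m$t) / np
}

#' Merge glioma tissue labels into evaluation regions
#'
#' The four glioma tissue classes (1 = necrotic core, 2 = oedema,
#' 3 = non-enhancing, 4 = enhancing core) are merged into the three nested
#' evaluation regions: *whole* tumor (all four classes), *core* tumor
#' (classes 1, 3, 4) and *enhancing* tumor (class 4 only).
#'
#' @param labels Integer array with values in `0..4`.
#' @return A list of three logical masks: `whole`, `core`, `enhancing`.
#' @examples
#' merge_brats_regions(c(0L, 1L, 2L, 3L, 4L))
#' @export
merge_brats_regions <- function(labels) {
  v <- as.integer(labels)
  if (anyNA(v) || any(v < 0L | v > 4L)) {
    stop("labels must be integers in 0..4", call. = FALSE)
  }
  shape_as <- function(mask) {
    if (!is.null(dim(labels))) array(mask, dim = dim(labels)) else mask
  }
  list(whole = shape_as(v > 0L),
       core = shape_as(v == 1L | v == 3L | v == 4L),
       enhancing = shape_as(v == 4L))
}

#' Evaluate predicted label volumes against ground truth
#'
#' Computes per-case Dice, sensitivity, specificity and precision, either for
#' the three merged glioma regions (`scheme = "brats"`) or for a single
#' binary lesion (`scheme = "binary"`), plus an unweighted mean over cases
#' (undefined scores excluded).
#'
#' @param predictions,truths Lists of integer label arrays (paired by
#'   position).
#' @param scheme `"brats"` or `"binary"`.
#' @return A data frame with one row per case and region, and mean rows
#'   (`case == "mean"`).
#' @export
evaluate_segmentation <- function(predictions, truths,
                                  scheme = c("brats", "binary")) {
  scheme <- match.arg(scheme)
  stopifnot(length(predictions) == length(truths))
  rows <- list()
  for (i in seq_along(predictions)) {
    masks <- if (scheme == "brats") {
      p <- merge_brats_regions(predictions[[i]])
      t <- merge_brats_regions(truths[[i]])
      lapply(names(p), function(r) list(region = r, p = p[[r]], t = t[[r]]))
    } else {
      list(list(region = "lesion",
                p = as.integer(predictions[[i]]) > 0L,
                t = as.integer(truths[[i]]) > 0L))
    }
    for (m in masks) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = as.character(i), region = m$region,
        dice = dice(m$p, m$t),
        sensitivity = sensitivity(m$p, m$t),
        specificity = specificity(m$p, m$t),
        precision = precision(m$p, m$t),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  for (r in unique(out$region)) {
    sub <- out[out$region == r, ]
    rows[[length(rows) + 1L]] <- data.frame(
      case = "mean", region = r,
      dice = mean(sub$dice, na.rm = TRUE),
      sensitivity = mean(sub$sensitivity, na.rm = TRUE),
      specificity = mean(sub$specificity, na.rm = TRUE),
      precision = mean(sub$precision, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[(length(rows) - length(unique(out$region)) + 1L):length(rows)]) -> means
  rbind(out, means)
}
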