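#' Read a single-modality 3D volume from a NIfTI file
#'
#' Reads one `.nii`/`.nii.gz` file into a plain 3D array in `[x, y, z]` order
#' together with its voxel spacing. Spacing is carried as metadata only; all
#' computation in this package operates on the voxel grid.
#'
#' @param path Path to a NIfTI file holding a single 3D volume.
#' @return A list with elements `data` (3D numeric array), `spacing` (numeric
#'   length-3, mm per voxel along x/y/z) and `header` (the NIfTI header, kept
#'   so that [write_volume()] can preserve orientation metadata).
#' @seealso [write_volume()], [stack_modalities()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("volume file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("not a single 3D volume (", paste(d, collapse = "x"), "): ", path,
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  list(data = array(as.numeric(img), dim = d),
       spacing = as.numeric(spacing),
       header = RNifti::niftiHeader(img))
}

#' Write a 3D volume to a NIfTI file
#'
#' Integer-valued arrays (e.g. label volumes) are written with an integer
#' datatype so that labels round-trip bit-exactly.
#'
#' @param data 3D array in `[x, y, z]` order.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param spacing Voxel size in mm along x/y/z.
#' @param integer Write with an integer on-disk datatype. Defaults to `TRUE`
#'   when `data` is an integer array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1),
                         integer = is.integer(data)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  attr(data, "pixdim") <- as.numeric(spacing)
  img <- RNifti::asNifti(data, datatype = if (integer) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble co-registered modality files into a multi-modality volume
#'
#' Each modality (e.g. T1, T1-contrast, T2, FLAIR for glioma; ADC and
#' perfusion maps for stroke) is one input channel of the segmentation
#' network. All files must share one grid shape.
#'
#' @param paths Character vector of NIfTI paths, or a list of 3D arrays. The
#'   modality axis of the result follows this order.
#' @param modalities Optional modality names; defaults to file basenames (or
#'   `mod1`, `mod2`, ... for arrays).
#' @return A `multimodal_volume`: a list with `data` (4D array
#'   `[x, y, z, modality]`), `modalities` (character) and `spacing`.
#' @examples
#' v1 <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' v2 <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' mm <- stack_modalities(list(v1, v2), modalities = c("T1", "FLAIR"))
#' dim(mm$data)
#' @export
stack_modalities <- function(paths, modalities = NULL) {
  if (is.character(paths)) {
    vols <- lapply(paths, read_volume)
    arrays <- lapply(vols, `[[`, "data")
    spacing <- vols[[1L]]$spacing
    if (is.null(modalities)) {
      modalities <- sub("\\.nii(\\.gz)?$", "", basename(paths))
    }
  } else if (is.list(paths)) {
    arrays <- paths
    spacing <- c(1, 1, 1)
    if (is.null(modalities)) modalities <- paste0("mod", seq_along(arrays))
  } else {
    stop("`paths` must be a character vector of files or a list of arrays",
         call. = FALSE)
  }
  if (length(arrays) < 1L) stop("at least one modality is required", call. = FALSE)
  shapes <- vapply(arrays, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("modalities do not share one grid shape: ",
         paste(shapes, collapse = ", "), call. = FALSE)
  }
  d <- dim(arrays[[1L]])
  data <- array(0, dim = c(d, length(arrays)))
  for (m in seq_along(arrays)) data[, , , m] <- arrays[[m]]
  multimodal_volume(data, modalities = modalities, spacing = spacing)
}

#' Construct a multi-modality volume from a 4D array
#'
#' @param data 4D array `[x, y, z, modality]`.
#' @param modalities Modality names (length = `dim(data)[4]`).
#' @param spacing Voxel size in mm along x/y/z.
#' @return A `multimodal_volume` object.
#' @export
multimodal_volume <- function(data, modalities = NULL, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (is.null(modalities)) modalities <- paste0("mod", seq_len(dim(data)[4L]))
  if (length(modalities) != dim(data)[4L]) {
    stop("need one modality name per channel", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("volume contains non-finite values", call. = FALSE)
  structure(list(data = data, modalities = as.character(modalities),
                 spacing = as.numeric(spacing)),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<multimodal_volume> ", d[1], "x", d[2], "x", d[3],
      " voxels, ", d[4], " modalities (",
      paste(x$modalities, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Per-modality z-scoring over nonzero voxels
#'
#' Standardizes each modality to zero mean and unit variance over its nonzero
#' voxels. Skull-stripped scans carry an exact-zero background; restricting
#' the statistics to nonzero voxels keeps that background at zero and makes
#' the standardization independent of how much empty space surrounds the
#' brain. A modality with constant nonzero foreground is mapped to zero
#' (zero-variance guard); an identically-zero modality is an error.
#'
#' The operation is idempotent on the foreground: re-normalizing changes
#' values by at most the numerical tolerance of the variance estimate.
#'
#' @param volume A `multimodal_volume` (see [stack_modalities()]).
#' @return The volume with each modality standardized.
#' @export
normalize_modalities <- function(volume) {
  stopifnot(inherits(volume, "multimodal_volume"))
  data <- volume$data
  for (m in seq_len(dim(data)[4L])) {
    v <- data[, , , m]
    fg <- v != 0
    if (!any(fg)) {
      stop("modality ", volume$modalities[m], " is identically zero",
           call. = FALSE)
    }
    mu <- mean(v[fg])
    sdev <- stats::sd(v[fg])
    if (!is.finite(sdev) || sdev == 0) {
      v[fg] <- 0
    } else {
      v[fg] <- (v[fg] - mu) / sdev
    }
    data[, , , m] <- v
  }
  volume$data <- data
  volume
}
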