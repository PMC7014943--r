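#' Configuration for synthetic multi-modality phantoms
#'
#' Phantoms emulate the structure of co-registered, skull-stripped
#' multi-modality brain MRI with labelled lesion compartments: a "brain"
#' ellipsoid positions the lesion, and nested axis-aligned ellipsoids carve
#' the lesion into compartments whose per-modality mean intensities differ by
#' class. Voxel intensity is the class's table entry plus additive Gaussian
#' noise, so with `noise_sigma = 0` every voxel equals its table entry
#' exactly, and with noise much smaller than the inter-class intensity gaps
#' the classes remain separable from intensity alone.
#'
#' In `"brats"` mode the compartments follow glioma anatomy: oedema
#' (label 2) outermost, then non-enhancing core (3), enhancing core (4), and
#' necrotic core (1) innermost, so necrotic voxels lie inside the enhancing
#' ellipsoid, which lies inside the oedema ellipsoid. In `"binary"` mode a
#' single irregular lesion (union of 2-3 overlapping ellipsoids) emulates
#' diffuse stroke outcome masks (label 1).
#'
#' @param shape Grid size `c(x, y, z)`; the slice axis is z.
#' @param mode `"brats"` (labels 0-4, default 4 modalities) or `"binary"`
#'   (labels 0/1, default 6 modalities).
#' @param n_modalities Number of modalities; defaults to 4 (brats) or 6
#'   (binary), matching the benchmark inputs the phantom emulates.
#' @param intensity_table Numeric matrix, one row per class (row order =
#'   `class_set`), one column per modality: mean intensity of that class in
#'   that modality. A default table with well-separated rows is supplied.
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise, in the same (arbitrary) units as the table. Must be >= 0.
#' @param brain_radius_fraction Brain ellipsoid semi-axis as a fraction of
#'   each half-extent.
#' @param lesion_radius_fractions Decreasing fractions of the brain radius
#'   giving the nested compartment ellipsoids (outermost first). In brats
#'   mode the four entries correspond to oedema, non-enhancing, enhancing and
#'   necrotic compartments.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical phantoms.
#' @return A `phantom_config` list.
#' @seealso [make_phantom()], [make_dataset()]
#' @export
phantom_config <- function(shape = c(96, 96, 24),
                           mode = c("brats", "binary"),
                           n_modalities = NULL,
                           intensity_table = NULL,
                           noise_sigma = 3,
                           brain_radius_fraction = 0.84,
                           lesion_radius_fractions = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_modalities)) n_modalities <- if (mode == "brats") 4L else 6L
  if (is.null(lesion_radius_fractions)) {
    lesion_radius_fractions <- if (mode == "brats") {
      c(oedema = 0.62, non_enhancing = 0.46, enhancing = 0.32, necrotic = 0.18)
    } else {
      c(lesion = 0.45)
    }
  }
  if (any(diff(lesion_radius_fractions) >= 0)) {
    stop("lesion_radius_fractions must be strictly decreasing (outer to inner)",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  class_set <- if (mode == "brats") 0:4 else 0:1
  if (is.null(intensity_table)) {
    intensity_table <- default_intensity_table(mode, n_modalities)
  }
  intensity_table <- as.matrix(intensity_table)
  if (nrow(intensity_table) != length(class_set)) {
    stop("intensity_table needs one row per class (",
         length(class_set), ")", call. = FALSE)
  }
  if (ncol(intensity_table) != n_modalities) {
    stop("intensity_table needs one column per modality (",
         n_modalities, ")", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), mode = mode,
                 n_modalities = as.integer(n_modalities),
                 class_set = class_set,
                 intensity_table = intensity_table,
                 noise_sigma = noise_sigma,
                 brain_radius_fraction = brain_radius_fraction,
                 lesion_radius_fractions = lesion_radius_fractions,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Default per-class mean intensities (arbitrary units, roughly T1/T1c/T2/FLAIR
# contrast patterns for brats; diffusion/perfusion-like contrasts for binary).
# Rows are well separated (minimum pairwise distance >> default noise_sigma).
default_intensity_table <- function(mode, n_modalities) {
  if (mode == "brats") {
    tab <- rbind(
      background    = c(60, 60, 70, 65),
      necrotic      = c(30, 25, 95, 75),
      oedema        = c(70, 65, 95, 110),
      non_enhancing = c(50, 45, 85, 88),
      enhancing     = c(55, 100, 78, 82)
    )
  } else {
    tab <- rbind(
      background = c(60, 55, 65, 60, 58, 62),
      lesion     = c(85, 90, 40, 38, 86, 35)
    )
  }
  if (n_modalities <= ncol(tab)) {
    tab <- tab[, seq_len(n_modalities), drop = FALSE]
  } else {
    extra <- ncol(tab) + seq_len(n_modalities - ncol(tab))
    tab <- cbind(tab, tab[, ((extra - 1L) %% ncol(tab)) + 1L, drop = FALSE])
  }
  unname(tab)
}

# Squared normalized ellipsoid coordinate for every voxel of an
# [x, y, z] grid; membership is value <= 1.
ellipsoid_field <- function(shape, center, radii) {
  gx <- (seq_len(shape[1]) - center[1]) / radii[1]
  gy <- (seq_len(shape[2]) - center[2]) / radii[2]
  gz <- (seq_len(shape[3]) - center[3]) / radii[3]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

#' Generate one synthetic multi-modality phantom
#'
#' @param config A [phantom_config()].
#' @param center Optional lesion centre in voxels (defaults to the grid
#'   centre); used by [make_dataset()] to jitter phantoms.
#' @param radius_scale Optional common scale factor applied to all lesion
#'   compartment radii.
#' @param use_seed Seed the generator from `config$seed` (set `FALSE` when a
#'   caller manages the random stream).
#' @return A list with `volume` (a `multimodal_volume`) and `labels`
#'   (integer 3D array on the same grid, values in `config$class_set`).
#' @examples
#' ph <- make_phantom(phantom_config(shape = c(32, 32, 8), noise_sigma = 0))
#' table(ph$labels)
#' @export
make_phantom <- function(config, center = NULL, radius_scale = 1,
                         use_seed = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  if (use_seed) set.seed(config$seed)
  shape <- config$shape
  half <- shape / 2
  brain_r <- config$brain_radius_fraction * half
  if (is.null(center)) center <- half + 0.5
  radii_frac <- config$lesion_radius_fractions * radius_scale
  radii <- lapply(radii_frac, function(f) f * brain_r)
  if (any(radii[[1L]] < 1)) {
    stop("outermost lesion radius below one voxel; enlarge the grid or radii",
         call. = FALSE)
  }
  # innermost-compartment-wins labelling over nested ellipsoids
  labels <- array(0L, dim = shape)
  if (config$mode == "brats") {
    lab_order <- c(2L, 3L, 4L, 1L)  # oedema, non-enh, enhancing, necrotic
    for (i in seq_along(radii)) {
      inside <- ellipsoid_field(shape, center, radii[[i]]) <= 1
      labels[inside] <- lab_order[i]
    }
  } else {
    n_blobs <- sample(2:3, 1L)
    for (b in seq_len(n_blobs)) {
      off <- runif(3, -0.35, 0.35) * radii[[1L]]
      r <- radii[[1L]] * runif(3, 0.55, 0.95)
      inside <- ellipsoid_field(shape, center + off, r) <= 1
      labels[inside] <- 1L
    }
  }
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(config$class_set, present)
  if (length(missing)) {
    stop("phantom grid too small: classes ", paste(missing, collapse = ","),
         " are empty; enlarge shape or radii", call. = FALSE)
  }
  data <- array(0, dim = c(shape, config$n_modalities))
  class_index <- match(labels, config$class_set)
  n <- prod(shape)
  for (m in seq_len(config$n_modalities)) {
    base <- config$intensity_table[class_index, m]
    noise <- if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma) else 0
    data[, , , m] <- array(base + noise, dim = shape)
  }
  mods <- if (config$mode == "brats") {
    c("T1", "T1c", "T2", "FLAIR")[seq_len(min(4L, config$n_modalities))]
  } else {
    c("TTP", "Tmax", "rCBV", "rCBF", "MTT", "ADC")[seq_len(min(6L, config$n_modalities))]
  }
  if (length(mods) < config$n_modalities) {
    mods <- c(mods, paste0("mod", seq.int(length(mods) + 1L, config$n_modalities)))
  }
  list(volume = multimodal_volume(data, modalities = mods),
       labels = labels)
}

#' Generate a reproducible dataset of jittered phantoms
#'
#' Phantoms differ by seeded jitter of the lesion centre and a common radius
#' scale; `n` and `seed` fully determine the output (each phantom draws from
#' a per-index substream so the dataset is reproducible element-wise).
#'
#' @param n Number of phantoms (>= 1).
#' @param config A [phantom_config()].
#' @param seed Integer seed for the dataset-level stream.
#' @return A list of `n` elements, each as returned by [make_phantom()].
#' @export
make_dataset <- function(n, config, seed = config$seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(inherits(config, "phantom_config"))
  lapply(seq_len(n), function(i) {
    set.seed(seed + 7919L * i)
    half <- config$shape / 2
    center <- half + 0.5 + runif(3, -0.12, 0.12) * half
    scale <- runif(1, 0.85, 1.1)
    make_phantom(config, center = center, radius_scale = scale,
                 use_seed = FALSE)
  })
}
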