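#' Segmentation network configuration
#'
#' Describes the architecture: four encoder blocks of 3x3x3 convolutions with
#' residual units and convolutional down-sampling, a refinement decoder that
#' maps each block to a constant channel width through 1x1x1 adaptive layers
#' and fuses coarse into fine features with x2 up-sampling, and a 1x1x1
#' classifier head with per-voxel softmax.
#'
#' Block 1 is two plain convolutions; blocks 2-4 each start with one strided
#' down-sampling convolution followed by `resblocks_per_block` residual units
#' (two convolutions each, identity shortcut). With the defaults this yields
#' exactly 17 backbone 3x3x3 convolutions. Down-sampling by default acts only
#' in-plane (stride `(2,2,1)` in `[x,y,z]`), keeping the slice axis at full
#' resolution through every layer; `depth_downsample = TRUE` halves the slice
#' axis as well.
#'
#' @param n_modalities Input channel count (4 for the glioma task, 6 for the
#'   stroke task).
#' @param n_classes Output classes including background (5 glioma, 2 stroke).
#' @param block_channels Widths of the four encoder blocks.
#' @param refine_channels Constant width of the refinement decoder (adaptive
#'   layers, refine units, and the features seen by the head).
#' @param resblocks_per_block Residual units per block; block 1 always uses
#'   two plain convolutions instead.
#' @param depth_downsample Also halve the slice axis at each down-sampling
#'   convolution.
#' @param upsample_mode Interpolation used by refine units on the coarse
#'   branch: `"trilinear"` (linear in the up-sampled dimensions) or
#'   `"nearest"`.
#' @return A `seg_config` list.
#' @export
seg_config <- function(n_modalities = 4L,
                       n_classes = 5L,
                       block_channels = c(32L, 64L, 128L, 256L),
                       refine_channels = 128L,
                       resblocks_per_block = c(0L, 2L, 2L, 2L),
                       depth_downsample = FALSE,
                       upsample_mode = c("trilinear", "nearest")) {
  upsample_mode <- match.arg(upsample_mode)
  if (length(block_channels) != 4L) {
    stop("block_channels must have length 4", call. = FALSE)
  }
  if (any(block_channels <= 0) || refine_channels <= 0 || n_modalities <= 0) {
    stop("channel counts must be positive", call. = FALSE)
  }
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  structure(list(n_modalities = as.integer(n_modalities),
                 n_classes = as.integer(n_classes),
                 block_channels = as.integer(block_channels),
                 refine_channels = as.integer(refine_channels),
                 resblocks_per_block = as.integer(resblocks_per_block),
                 depth_downsample = isTRUE(depth_downsample),
                 upsample_mode = upsample_mode),
            class = "seg_config")
}

# Ordered layer table: one row per convolution with its geometry and
# attachments. This single table drives parameter construction, the forward
# and backward passes, parameter counting and the printed description.
seg_layer_table <- function(cfg) {
  ch <- cfg$block_channels
  r <- cfg$refine_channels
  s2 <- if (cfg$depth_downsample) "2,2,2" else "2,2,1"
  rows <- list()
  add <- function(name, role, k, stride, cin, cout, bn, bias) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, role = role, kernel = k, stride = stride,
      cin = cin, cout = cout, bn = bn, bias = bias,
      stringsAsFactors = FALSE)
  }
  add("b1c1", "backbone", 3L, "1,1,1", cfg$n_modalities, ch[1], TRUE, FALSE)
  add("b1c2", "backbone", 3L, "1,1,1", ch[1], ch[1], TRUE, FALSE)
  for (b in 2:4) {
    add(paste0("b", b, "d"), "backbone", 3L, s2, ch[b - 1], ch[b], TRUE, FALSE)
    for (j in seq_len(cfg$resblocks_per_block[b])) {
      add(paste0("b", b, "r", j, "c1"), "backbone", 3L, "1,1,1", ch[b], ch[b], TRUE, FALSE)
      add(paste0("b", b, "r", j, "c2"), "backbone", 3L, "1,1,1", ch[b], ch[b], TRUE, FALSE)
    }
  }
  for (i in 1:4) {
    add(paste0("adapt", i), "adaptive", 1L, "1,1,1", ch[i], r, TRUE, FALSE)
  }
  for (i in 3:1) {
    add(paste0("ref", i, "_fine"), "refine", 1L, "1,1,1", r, r, FALSE, TRUE)
    add(paste0("ref", i, "_coarse"), "refine", 1L, "1,1,1", r, r, FALSE, TRUE)
    add(paste0("ref", i, "_post"), "refine", 3L, "1,1,1", r, r, TRUE, FALSE)
  }
  add("head", "head", 1L, "1,1,1", r, cfg$n_classes, FALSE, TRUE)
  tab <- do.call(rbind, rows)
  tab$n_params <- tab$cout * tab$cin * tab$kernel^3 +
    ifelse(tab$bn, 2L * tab$cout, 0L) + ifelse(tab$bias, tab$cout, 0L)
  tab
}

#' Build an (untrained) segmentation network
#'
#' Instantiates parameters for the architecture described by a
#' [seg_config()]: He fan-in initialized convolution weights, unit-gain batch
#' normalization, zero biases.
#'
#' @param config A [seg_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return A `segnet` object: `config`, flat named `params` list, batch-norm
#'   running-moment `buffers`, and the per-layer table (see
#'   [describe_network()]).
#' @examples
#' m <- build_model(seg_config())
#' describe_network(m)$backbone_conv_count
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "seg_config"))
  if (!is.null(seed)) set.seed(seed)
  tab <- seg_layer_table(config)
  params <- list()
  buffers <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    fan_in <- tab$cin[i] * tab$kernel[i]^3
    params[[paste0(nm, ".W")]] <-
      matrix(rnorm(tab$cout[i] * fan_in, sd = sqrt(2 / fan_in)),
             nrow = tab$cout[i], ncol = fan_in)
    if (tab$bn[i]) {
      params[[paste0(nm, ".g")]] <- rep(1, tab$cout[i])
      params[[paste0(nm, ".b")]] <- rep(0, tab$cout[i])
      buffers[[paste0(nm, ".rm")]] <- rep(0, tab$cout[i])
      buffers[[paste0(nm, ".rv")]] <- rep(1, tab$cout[i])
    }
    if (tab$bias[i]) params[[paste0(nm, ".bias")]] <- rep(0, tab$cout[i])
  }
  structure(list(config = config, params = params, buffers = buffers,
                 layers = tab),
            class = "segnet")
}

#' Per-layer description and parameter accounting of a network
#'
#' @param model A `segnet` (from [build_model()]) or a fitted [brainseg()]
#'   object.
#' @return A list with `layers` (data frame: name, role, kernel, stride,
#'   in/out channels, parameter count), `total_parameters`, and
#'   `backbone_conv_count` (3x3x3 encoder convolutions only; adaptive layers,
#'   refine units and the head are counted in `total_parameters` but not
#'   here).
#' @export
describe_network <- function(model) {
  if (inherits(model, "brainseg")) model <- model$model
  stopifnot(inherits(model, "segnet"))
  tab <- model$layers
  total <- sum(tab$n_params)
  stopifnot(total == sum(lengths(model$params)))
  list(layers = tab,
       total_parameters = total,
       backbone_conv_count = sum(tab$role == "backbone" & tab$kernel == 3L))
}

#' @export
print.segnet <- function(x, ...) {
  d <- describe_network(x)
  cat("<segnet> ", x$config$n_modalities, " modalities -> ",
      x$config$n_classes, " classes\n", sep = "")
  cat("  encoder widths: ", paste(x$config$block_channels, collapse = "/"),
      ", refine width: ", x$config$refine_channels, "\n", sep = "")
  cat("  backbone 3x3x3 convolutions: ", d$backbone_conv_count,
      "; trainable parameters: ",
      format(d$total_parameters, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Feature-map shapes per encoder block
#'
#' In-plane extents scale by 1, 1/2, 1/4, 1/8 across blocks 1-4; the slice
#' axis is unchanged unless `depth_downsample` is set.
#'
#' @param config A [seg_config()].
#' @param input_shape Grid size `c(x, y, z)`.
#' @return Data frame with one row per block: extents and channel width.
#' @examples
#' feature_shapes(seg_config(), c(128, 128, 12))
#' @export
feature_shapes <- function(config, input_shape) {
  stopifnot(inherits(config, "seg_config"), length(input_shape) == 3L)
  f <- c(1L, 2L, 4L, 8L)
  fz <- if (config$depth_downsample) f else rep(1L, 4L)
  data.frame(block = 1:4,
             x = as.integer(input_shape[1] / f),
             y = as.integer(input_shape[2] / f),
             z = as.integer(input_shape[3] / fz),
             channels = config$block_channels)
}

# Validates that a grid can pass through three x2 down-samplings.
check_divisible <- function(config, shape) {
  if (shape[1] %% 8L != 0L || shape[2] %% 8L != 0L) {
    stop("in-plane extents must be multiples of 8 (three x2 down-samplings); ",
         "got ", shape[1], "x", shape[2], call. = FALSE)
  }
  if (config$depth_downsample && shape[3] %% 8L != 0L) {
    stop("with depth_downsample the slice extent must be a multiple of 8; ",
         "got ", shape[3], call. = FALSE)
  }
  invisible(TRUE)
}
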