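#' Fit a 3D residual refinement segmentation network
#'
#' The main entry point: trains the segmentation network on a list of
#' labelled multi-modality scans using the three-stage curriculum (or any
#' configured stage list) and returns a fitted-model object with the usual
#' methods (`print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#' `simulate`).
#'
#' @param data List of scans; each element is a list with `volume` (a
#'   `multimodal_volume` or 4D array `[x, y, z, modality]`) and `labels`
#'   (integer array of 0-based class labels on the same grid). The phantom
#'   generator ([make_dataset()]) produces this structure.
#' @param model A [seg_config()] describing the architecture, or an already
#'   built/partially trained `segnet` to continue from.
#' @param control A [train_config()].
#' @param normalize Apply [normalize_modalities()] to every scan before
#'   training (predictions then normalize new data the same way).
#' @return A `brainseg` object: the trained `segnet` (`$model`), per-stage
#'   loss `$histories`, the configurations used, and the matched call.
#' @examples
#' \donttest{
#' ph <- make_dataset(2, phantom_config(shape = c(32, 32, 8), mode = "binary"))
#' fit <- brainseg(ph,
#'                 model = desk_config(n_modalities = 6, n_classes = 2),
#'                 control = desk_train_config(epochs = 2,
#'                                             window_depth = 8,
#'                                             crop_size = c(32, 32)))
#' pred <- predict(fit, ph[[1]]$volume)
#' dice(pred > 0, ph[[1]]$labels > 0)
#' }
#' @export
brainseg <- function(data, model = seg_config(),
                     control = train_config(), normalize = TRUE) {
  cl <- match.call()
  stopifnot(is.list(data), length(data) >= 1L)
  if (inherits(model, "seg_config")) {
    set.seed(control$seed)
    model <- build_model(model)
  }
  stopifnot(inherits(model, "segnet"))
  prep <- lapply(data, function(scan) {
    vol <- scan$volume
    if (!inherits(vol, "multimodal_volume")) vol <- multimodal_volume(vol)
    if (dim(vol$data)[4] != model$config$n_modalities) {
      stop("scan has ", dim(vol$data)[4], " modalities but the model expects ",
           model$config$n_modalities, call. = FALSE)
    }
    if (normalize) vol <- normalize_modalities(vol)
    list(volume = vol, labels = scan$labels)
  })
  res <- run_curriculum(model, prep, control)
  structure(list(model = res$model, histories = res$histories,
                 control = control, normalize = normalize, call = cl),
            class = "brainseg")
}

#' @export
print.brainseg <- function(x, ...) {
  cat("3D residual refinement segmentation network\n\n")
  print(x$model)
  st <- names(x$histories)
  cat("  curriculum: ", length(st), " stage(s) — ",
      paste(st, collapse = " -> "), "\n", sep = "")
  last <- vapply(x$histories, function(h) h[length(h)], numeric(1))
  cat("  final epoch mean loss per stage: ",
      paste(signif(last, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.brainseg <- function(object, ...) {
  d <- describe_network(object$model)
  structure(list(description = d, histories = object$histories,
                 config = object$model$config), class = "summary.brainseg")
}

#' @export
print.summary.brainseg <- function(x, ...) {
  cat("Network layers:\n")
  print(x$description$layers, row.names = FALSE)
  cat("\nTotal trainable parameters: ",
      format(x$description$total_parameters, big.mark = ","),
      " (backbone 3x3x3 convolutions: ",
      x$description$backbone_conv_count, ")\n", sep = "")
  for (nm in names(x$histories)) {
    h <- x$histories[[nm]]
    cat(sprintf("Stage %-18s %4d epochs, loss %.5f -> %.5f\n",
                nm, length(h), h[1], h[length(h)]))
  }
  invisible(x)
}

#' @export
coef.brainseg <- function(object, ...) object$model$params

#' Predict a segmentation for a new scan
#'
#' Runs memory-bounded sliding-window inference: the scan is split into
#' full-plane sub-volumes along the slice axis, each sub-volume is passed
#' through the network in evaluation mode, the per-window probabilities are
#' stitched back to full depth, and (for `type = "class"`) the per-voxel
#' argmax is taken, with ties broken toward the lower class index.
#'
#' @param object A fitted [brainseg()] model or a `segnet`.
#' @param newdata A `multimodal_volume` or 4D array `[x, y, z, modality]`
#'   whose in-plane extents are multiples of 8.
#' @param type `"class"` for an integer label volume, `"prob"` for the
#'   `[x, y, z, K]` probability array.
#' @param subvolume_depth Slices per inference sub-volume; `NULL` predicts
#'   the whole scan in one pass.
#' @param normalize Standardize modalities first; defaults to how the model
#'   was fitted (`TRUE` for a bare `segnet` only if requested).
#' @param ... Unused.
#' @return Integer label array or probability array.
#' @export
predict.brainseg <- function(object, newdata, type = c("class", "prob"),
                             subvolume_depth = NULL,
                             normalize = object$normalize, ...) {
  predict(object$model, newdata, type = type,
          subvolume_depth = subvolume_depth, normalize = normalize)
}

#' @rdname predict.brainseg
#' @export
predict.segnet <- function(object, newdata, type = c("class", "prob"),
                           subvolume_depth = NULL, normalize = FALSE, ...) {
  type <- match.arg(type)
  vol <- if (inherits(newdata, "multimodal_volume")) newdata else {
    multimodal_volume(newdata)
  }
  if (normalize) vol <- normalize_modalities(vol)
  d <- dim(vol$data)
  check_divisible(object$config, d[1:3])
  if (d[4] != object$config$n_modalities) {
    stop("expected ", object$config$n_modalities, " modalities, got ", d[4],
         call. = FALSE)
  }
  run_one <- function(a) {
    dims <- dim(a)[1:3]
    fw <- nn_forward(object, vol_to_mat(a), dims, B = 1L, training = FALSE)
    array(t(softmax_cols(fw$logits)),
          dim = c(dims, object$config$n_classes))
  }
  prob <- if (is.null(subvolume_depth) || subvolume_depth >= d[3]) {
    run_one(vol$data)
  } else {
    sp <- split_inference(vol$data, subvolume_depth)
    stitch(lapply(sp$subvolumes, run_one), sp$plan)
  }
  if (type == "prob") prob else predict_labels(prob)
}

#' @export
plot.brainseg <- function(x, ...) {
  hs <- x$histories
  all_loss <- unlist(hs)
  bounds <- cumsum(c(0, vapply(hs, length, integer(1))))
  plot(seq_along(all_loss), all_loss, type = "l",
       xlab = "epoch (stages concatenated)", ylab = "mean training loss",
       main = "Curriculum training loss", ...)
  if (length(hs) > 1L) {
    abline(v = bounds[2:(length(bounds) - 1L)] + 0.5, lty = 3)
  }
  invisible(x)
}

#' Per-voxel residuals of a fitted segmentation model
#'
#' For each scan, returns `1 - p_true`: one minus the probability the model
#' assigns to the voxel's true class. Zero means a confidently correct voxel.
#'
#' @param object A fitted [brainseg()] model.
#' @param data List of scans with `volume` and `labels` (defaults cannot be
#'   stored, so the training data must be passed back in).
#' @param ... Unused.
#' @return A list of 3D arrays of residuals in `[0, 1]`.
#' @export
residuals.brainseg <- function(object, data, ...) {
  lapply(data, function(scan) {
    prob <- predict(object, scan$volume, type = "prob")
    d <- dim(prob)
    K <- d[4]
    pm <- t(matrix(prob, nrow = prod(d[1:3]), ncol = K))
    tg <- as.integer(scan$labels)
    pt <- pm[(seq_along(tg) - 1L) * K + tg + 1L]
    array(1 - pt, dim = d[1:3])
  })
}

#' Simulate label volumes from a fitted segmentation model
#'
#' Draws label volumes by sampling each voxel's class from the model's
#' predicted class probabilities (independently across voxels).
#'
#' @param object A fitted [brainseg()] model.
#' @param nsim Number of simulated label volumes.
#' @param seed Optional integer seed.
#' @param newdata Scan to predict on (`multimodal_volume` or 4D array).
#' @param ... Unused.
#' @return A list of `nsim` integer label arrays.
#' @export
simulate.brainseg <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  prob <- predict(object, newdata, type = "prob")
  d <- dim(prob)
  K <- d[4]
  pm <- matrix(prob, nrow = prod(d[1:3]), ncol = K)
  cum <- pm %*% upper.tri(diag(K), diag = TRUE)
  lapply(seq_len(nsim), function(i) {
    u <- runif(nrow(pm))
    lab <- rowSums(u > cum)  # counts of cumulative bins below u
    array(as.integer(pmin(lab, K - 1L)), dim = d[1:3])
  })
}
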