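#' Curriculum stages
#'
#' One stage of the training curriculum: how many epochs to run, which
#' fraction of samples receives data augmentation, and which loss is used.
#' The three-stage default increases data complexity gradually: stage 1
#' trains on original data with cross-entropy (the "easy task"), stage 2
#' augments 50% of samples (still cross-entropy), and stage 3 switches to the
#' focal loss while augmenting 75% of samples. Stages are continuations —
#' each starts from the previous stage's weights.
#'
#' @param name Stage label.
#' @param epochs Epochs to run in this stage (> 0).
#' @param augment_fraction Probability that a sample is augmented.
#' @param loss `"ce"` (cross-entropy) or `"focal"`.
#' @param gamma Focusing parameter for the focal loss (ignored for `"ce"`;
#'   `gamma = 0` makes focal identical to cross-entropy).
#' @return A `curriculum_stage` list.
#' @export
curriculum_stage <- function(name, epochs, augment_fraction,
                             loss = c("ce", "focal"), gamma = 2) {
  loss <- match.arg(loss)
  if (epochs <= 0) stop("epochs must be > 0", call. = FALSE)
  if (augment_fraction < 0 || augment_fraction > 1) {
    stop("augment_fraction must be in [0, 1]", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(name = name, epochs = as.integer(epochs),
                 augment_fraction = augment_fraction,
                 loss = loss, gamma = gamma),
            class = "curriculum_stage")
}

#' The default three-stage curriculum
#'
#' @param gamma Focal-loss focusing parameter for the final stage.
#' @param epochs Epochs per stage (500 each by default, i.e. 1500 in total).
#' @return A list of three [curriculum_stage()] objects with augmentation
#'   fractions 0, 0.5 and 0.75.
#' @examples
#' sapply(default_curriculum(), `[[`, "augment_fraction")
#' @export
default_curriculum <- function(gamma = 2, epochs = 500L) {
  list(curriculum_stage("original", epochs, 0, "ce"),
       curriculum_stage("augment50", epochs, 0.5, "ce"),
       curriculum_stage("focal_augment75", epochs, 0.75, "focal", gamma = gamma))
}

#' Training configuration
#'
#' @param stages List of [curriculum_stage()]s (one stage gives the
#'   no-curriculum ablation baseline).
#' @param learning_rate Adam step size (default `1e-4`, constant across
#'   stages).
#' @param batch_size Patches per optimizer step (default 40).
#' @param window_depth Slices per training patch.
#' @param crop_size In-plane patch size `c(x, y)` (multiples of 8).
#' @param augment An [augment_config()]; its `apply_prob` is overridden per
#'   stage, and its `crop_size` is forced to the full scan plane (patch
#'   cropping is done by [extract_training_patches()]).
#' @param seed Integer seed governing initialization, cropping, augmentation
#'   and batch shuffling.
#' @param checkpoint_dir Directory for per-stage checkpoints (`NULL`
#'   disables checkpointing).
#' @param reset_optimizer Reset Adam moment estimates at stage boundaries
#'   (each stage is treated as a new task); set `FALSE` to carry state over.
#' @return A `train_config` list.
#' @export
train_config <- function(stages = default_curriculum(),
                         learning_rate = 1e-4,
                         batch_size = 40L,
                         window_depth = 12L,
                         crop_size = c(128L, 128L),
                         augment = augment_config(),
                         seed = 1L,
                         checkpoint_dir = NULL,
                         reset_optimizer = TRUE) {
  if (length(stages) < 1L) stop("at least one stage is required", call. = FALSE)
  if (inherits(stages, "curriculum_stage")) stages <- list(stages)
  if (learning_rate <= 0 && learning_rate != 0) {
    stop("learning_rate must be >= 0", call. = FALSE)
  }
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(stages = stages, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 window_depth = as.integer(window_depth),
                 crop_size = as.integer(crop_size),
                 augment = augment, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 reset_optimizer = isTRUE(reset_optimizer)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A named reduced configuration for CPU-scale experiments and tests: small
#' patches (8 slices, 32x32 in-plane), batch size 2, 20 epochs per stage and
#' a learning rate of `1e-3` (scaled up from the full regime's `1e-4`
#' because the desk run takes two orders of magnitude fewer optimizer
#' steps). Pair it with [desk_config()] for a matching small network.
#'
#' @param gamma Focal-loss focusing parameter for stage 3.
#' @param epochs Epochs per stage.
#' @param ... Passed on to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(gamma = 2, epochs = 20L, ...) {
  train_config(stages = default_curriculum(gamma = gamma, epochs = epochs),
               learning_rate = 1e-3,
               batch_size = 2L,
               window_depth = 8L,
               crop_size = c(32L, 32L),
               ...)
}

#' Desk-scale network profile
#'
#' @param n_modalities,n_classes As in [seg_config()].
#' @return A [seg_config()] with block channels 8/16/32/64 and refine width
#'   16 — the same topology (and the same 17 backbone convolutions) at a
#'   width a single CPU trains in minutes.
#' @export
desk_config <- function(n_modalities = 4L, n_classes = 5L) {
  seg_config(n_modalities = n_modalities, n_classes = n_classes,
             block_channels = c(8L, 16L, 32L, 64L),
             refine_channels = 16L)
}

# ---- Adam optimizer over a flat named parameter list ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# One optimizer step on a batch of patches (list of x/y pairs with identical
# dims). Returns updated model/opt state and the batch mean loss.
train_batch <- function(model, batch, opt, lr, loss, gamma) {
  dims <- dim(batch[[1L]]$x)[1:3]
  B <- length(batch)
  x <- do.call(cbind, lapply(batch, function(p) vol_to_mat(p$x)))
  tg <- unlist(lapply(batch, function(p) as.integer(p$y)))
  fw <- nn_forward(model, x, dims, B = B, training = TRUE)
  model$buffers <- fw$buffers
  p <- softmax_cols(fw$logits)
  K <- nrow(p)
  idx <- (seq_along(tg) - 1L) * K + tg + 1L
  pt <- pmin(pmax(p[idx], 1e-7), 1)
  g_eff <- if (loss == "ce") 0 else gamma
  loss_val <- mean((1 - pt)^g_eff * (-log(pt)))
  if (!is.finite(loss_val)) {
    stop("non-finite training loss; batch logit range: ",
         paste(signif(range(fw$logits), 4), collapse = " .. "), call. = FALSE)
  }
  if (lr > 0) {
    dlogits <- focal_grad_logits(p, tg, g_eff)
    grads <- nn_backward(model, fw, dlogits)
    st <- adam_step(model$params, grads, opt, lr)
    model$params <- st$params
    opt <- st$state
  }
  list(model = model, opt = opt, loss = loss_val)
}

#' Train one curriculum stage
#'
#' Runs `stage$epochs` epochs of Adam on patches pooled from all scans. Each
#' epoch re-draws the augmentation decisions (with probability
#' `stage$augment_fraction` per scan) and the ROI-constrained random crops,
#' then shuffles the pooled patches into batches. Weights continue from the
#' model passed in, so successive stages are continuations.
#'
#' @param model A `segnet` (see [build_model()]).
#' @param dataset List of scans: each element has `volume` (a
#'   `multimodal_volume` or 4D array) and `labels` (integer array, 0-based
#'   classes).
#' @param stage A [curriculum_stage()].
#' @param config A [train_config()].
#' @param opt Optional Adam state to continue from.
#' @return List with `model`, `history` (per-epoch mean loss) and `opt`.
#' @export
train_stage <- function(model, dataset, stage, config, opt = NULL) {
  stopifnot(inherits(model, "segnet"), inherits(stage, "curriculum_stage"),
            inherits(config, "train_config"))
  if (is.null(opt)) opt <- adam_init(model$params)
  aug <- config$augment
  aug$apply_prob <- stage$augment_fraction
  history <- numeric(stage$epochs)
  for (epoch in seq_len(stage$epochs)) {
    patches <- list()
    for (scan in dataset) {
      vol <- if (inherits(scan$volume, "multimodal_volume")) {
        scan$volume$data
      } else {
        scan$volume
      }
      lab <- scan$labels
      aug_full <- aug
      aug_full$crop_size <- dim(vol)[1:2]
      ma <- maybe_augment(vol, lab, aug_full)
      patches <- c(patches,
                   extract_training_patches(ma$volume, ma$labels,
                                            config$window_depth,
                                            config$crop_size))
    }
    patches <- patches[sample.int(length(patches))]
    losses <- c()
    i <- 1L
    while (i <= length(patches)) {
      j <- min(i + config$batch_size - 1L, length(patches))
      tb <- train_batch(model, patches[i:j], opt, config$learning_rate,
                        stage$loss, stage$gamma)
      model <- tb$model
      opt <- tb$opt
      losses <- c(losses, tb$loss)
      i <- j + 1L
    }
    history[epoch] <- mean(losses)
  }
  list(model = model, history = history, opt = opt)
}

#' Run the full curriculum
#'
#' Executes the configured stages in order, carrying weights (and, if
#' `reset_optimizer = FALSE`, optimizer state) across stage boundaries, and
#' writes a checkpoint after each stage when `checkpoint_dir` is set.
#'
#' @inheritParams train_stage
#' @return List with the trained `model` and `histories` (named per-stage
#'   numeric vectors of epoch mean losses).
#' @export
run_curriculum <- function(model, dataset, config) {
  stopifnot(inherits(config, "train_config"))
  set.seed(config$seed)
  histories <- list()
  opt <- NULL
  for (k in seq_along(config$stages)) {
    stage <- config$stages[[k]]
    if (config$reset_optimizer) opt <- NULL
    res <- train_stage(model, dataset, stage, config, opt = opt)
    model <- res$model
    opt <- res$opt
    histories[[stage$name]] <- res$history
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(config = model$config, params = model$params,
                   buffers = model$buffers),
              file.path(config$checkpoint_dir,
                        sprintf("stage%02d_%s.rds", k, stage$name)))
    }
  }
  list(model = model, histories = histories)
}
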