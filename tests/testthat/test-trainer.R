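# Small shared setup: two tiny binary phantoms and a matching micro network.
tiny_setup <- function(seed = 1L) {
  cfg <- phantom_config(shape = c(16L, 16L, 8L), mode = "binary",
                        n_modalities = 2L, seed = seed)
  list(data = make_dataset(2, cfg, seed = seed),
       model_cfg = micro_config(n_modalities = 2L, n_classes = 2L))
}

tiny_control <- function(stages, seed = 1L, lr = 1e-3, ...) {
  train_config(stages = stages, learning_rate = lr, batch_size = 2L,
               window_depth = 4L, crop_size = c(8L, 8L), seed = seed, ...)
}

test_that("the default curriculum follows the three published stages", {
  cur <- default_curriculum()
  expect_length(cur, 3L)
  expect_equal(vapply(cur, `[[`, numeric(1), "augment_fraction"),
               c(0, 0.5, 0.75))
  expect_equal(vapply(cur, `[[`, character(1), "loss"),
               c("ce", "ce", "focal"))
  expect_equal(vapply(cur, `[[`, integer(1), "epochs"), rep(500L, 3))
  expect_error(curriculum_stage("x", 0, 0), "epochs")
  expect_error(curriculum_stage("x", 1, 2), "augment_fraction")
})

test_that("a zero learning rate leaves the weights unchanged", {
  ts <- tiny_setup()
  model <- build_model(ts$model_cfg, seed = 2)
  before <- model$params
  set.seed(3)
  res <- train_stage(model, ts$data,
                     curriculum_stage("null", 1, 0, "ce"),
                     tiny_control(default_curriculum(epochs = 1), lr = 0))
  expect_identical(res$model$params, before)
  expect_length(res$history, 1L)
  expect_true(is.finite(res$history))
})

test_that("identical seeds reproduce the loss history exactly", {
  ts <- tiny_setup()
  ctrl <- tiny_control(default_curriculum(epochs = 2), seed = 9)
  run <- function() {
    model <- build_model(ts$model_cfg, seed = 9)
    run_curriculum(model, ts$data, ctrl)
  }
  a <- run()
  b <- run()
  expect_identical(a$histories, b$histories)
  expect_identical(a$model$params, b$model$params)
  expect_true(all(is.finite(unlist(a$histories))))
})

test_that("stages are continuations and checkpoints are written", {
  ts <- tiny_setup()
  ck <- file.path(tempfile("ckpt"), "run1")
  ctrl <- tiny_control(default_curriculum(epochs = 2), seed = 4,
                       checkpoint_dir = ck)
  model <- build_model(ts$model_cfg, seed = 4)
  res <- run_curriculum(model, ts$data, ctrl)
  expect_length(res$histories, 3L)
  expect_length(list.files(ck, pattern = "\\.rds$"), 3L)
  # weights moved away from both the init and the previous stage
  expect_false(identical(res$model$params, model$params))
  # single-stage ablation emits a single checkpoint
  ck2 <- file.path(tempfile("ckpt"), "ablation")
  ctrl1 <- tiny_control(list(curriculum_stage("only", 2, 0, "ce")),
                        seed = 4, checkpoint_dir = ck2)
  run_curriculum(build_model(ts$model_cfg, seed = 4), ts$data, ctrl1)
  expect_length(list.files(ck2, pattern = "\\.rds$"), 1L)
})

test_that("focal training with gamma 0 is byte-identical to cross-entropy", {
  ts <- tiny_setup()
  model <- build_model(ts$model_cfg, seed = 5)
  run_with <- function(stage) {
    set.seed(6)
    train_stage(model, ts$data, stage,
                tiny_control(default_curriculum(epochs = 2)))
  }
  ce <- run_with(curriculum_stage("ce", 2, 0, "ce"))
  f0 <- run_with(curriculum_stage("f0", 2, 0, "focal", gamma = 0))
  expect_identical(ce$history, f0$history)
  expect_identical(ce$model$params, f0$model$params)
})

test_that("a short seeded run reduces the training loss on phantoms", {
  ts <- tiny_setup(seed = 8)
  model <- build_model(ts$model_cfg, seed = 8)
  res <- train_stage(model, ts$data,
                     curriculum_stage("smoke", 8, 0, "ce"),
                     tiny_control(default_curriculum(epochs = 8), seed = 8))
  expect_lt(res$history[length(res$history)], res$history[1])
  expect_true(all(is.finite(res$history)))
})

test_that("fitted models expose the standard S3 interface", {
  ts <- tiny_setup(seed = 12)
  fit <- brainseg(ts$data, model = ts$model_cfg,
                  control = tiny_control(default_curriculum(epochs = 2),
                                         seed = 12))
  expect_s3_class(fit, "brainseg")
  expect_output(print(fit), "curriculum")
  expect_output(print(summary(fit)), "Total trainable parameters")
  expect_named(coef(fit), names(fit$model$params), ignore.order = TRUE)
  pred <- predict(fit, ts$data[[1]]$volume, subvolume_depth = 4)
  expect_equal(dim(pred), c(16, 16, 8))
  expect_true(all(pred %in% 0:1))
  prob <- predict(fit, ts$data[[1]]$volume, type = "prob")
  expect_equal(dim(prob), c(16, 16, 8, 2))
  res <- residuals(fit, ts$data[1])
  expect_length(res, 1L)
  expect_true(all(res[[1]] >= 0 & res[[1]] <= 1))
  sims <- simulate(fit, nsim = 2, seed = 1, newdata = ts$data[[1]]$volume)
  expect_length(sims, 2L)
  expect_true(all(unlist(sims) %in% 0:1))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
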