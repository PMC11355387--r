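test_that("pixel cross-entropy matches closed forms and a hand-summed oracle", {
  y <- rand_mask(4, 4, seed = 1)
  # perfect prediction: only the clipping contributes
  expect_lt(pixel_cross_entropy(y + 0, y), 1e-6)
  # maximum-uncertainty prediction: log 2 for any mask
  expect_equal(pixel_cross_entropy(matrix(0.5, 4, 4), y), log(2))
  # random case against an explicit per-pixel sum
  set.seed(2)
  p <- matrix(runif(16), 4, 4)
  acc <- 0
  for (i in 1:4)
    for (j in 1:4)
      acc <- acc - (y[i, j] * log(p[i, j]) + (1 - y[i, j]) * log(1 - p[i, j]))
  expect_equal(pixel_cross_entropy(p, y), acc / 16)
  # bounds: 0 <= loss <= -log(eps)
  worst <- matrix(1e-12, 4, 4)
  expect_lte(pixel_cross_entropy(worst, matrix(1L, 4, 4)), -log(1e-7) + 1e-9)
  expect_error(pixel_cross_entropy(matrix(0.5, 2, 3), y), "differ")
})

make_tiny_split <- function(n = 4, seed = 1, model_size = 32L) {
  scenes <- lapply(seq_len(n), function(i)
    generate_scene(small_params(seed = seed * 100 + i)))
  build_dataset(scenes, train_fraction = 0.5, val_fraction = 0.25,
                seed = seed, model_size = model_size)
}

test_that("200 gradient steps on one tile drive the loss down for every architecture", {
  ds <- make_tiny_split()
  tile <- ds$train_tiles[[1]]
  for (arch in c("unet", "deeplabv3plus", "unet_xception")) {
    model <- build_seg_model(tiny_spec(arch))
    adam <- opuntiaseg:::adam_new(model$params)
    loss0 <- NULL
    for (step in 1:200) {
      r <- opuntiaseg:::tile_grad(model, tile, 1)
      if (step == 1) loss0 <- r$loss
      upd <- opuntiaseg:::adam_step(model$params, r$grads, adam, 1e-3)
      model$params <- upd$params
      adam <- upd$state
    }
    final <- opuntiaseg:::tile_grad(model, tile, 1)$loss
    expect_lt(final, loss0)
    expect_lt(final, 0.2)   # a single tile should be near-memorised
  }
})

test_that("training checkpoints the best validation epoch and is deterministic", {
  ds <- make_tiny_split(seed = 3)
  ctrl <- train_control(epochs = 2, batch_size = 4, seed = 11)
  fit <- fit_segmenter(ds, spec = tiny_spec("deeplabv3plus"), control = ctrl)
  h <- fit$history
  expect_equal(nrow(h$metrics), 2L)
  expect_equal(h$best_val_iou, max(h$metrics$val_iou))
  expect_equal(h$metrics$val_iou[h$best_epoch], h$best_val_iou)

  # the returned model re-evaluates to the checkpointed validation IoU
  ev <- evaluate_tiles(fit$model, ds$validation_tiles, ctrl$threshold)
  expect_equal(ev$mean_iou, h$best_val_iou, tolerance = 1e-6)
  expect_gte(ev$mean_iou + 1e-6, max(h$metrics$val_iou))

  # seed determinism on CPU
  fit2 <- fit_segmenter(ds, spec = tiny_spec("deeplabv3plus"), control = ctrl)
  expect_identical(fit$history$metrics, fit2$history$metrics)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("a single-epoch fit selects epoch one", {
  ds <- make_tiny_split(seed = 4)
  fit <- fit_segmenter(ds, spec = tiny_spec("unet"),
                       control = train_control(epochs = 1, batch_size = 4))
  expect_equal(fit$history$best_epoch, 1L)
})

test_that("an empty validation set is rejected at training time", {
  scenes <- lapply(1:4, function(i) generate_scene(small_params(seed = 40 + i)))
  ds <- build_dataset(scenes, train_fraction = 0.5, val_fraction = 0,
                      seed = 1, model_size = 32)
  expect_error(fit_segmenter(ds, spec = tiny_spec("unet")), "validation")
})

test_that("seg_fit methods print, summarise, plot and predict", {
  ds <- make_tiny_split(seed = 5)
  fit <- fit_segmenter(ds, spec = tiny_spec("deeplabv3plus"),
                       control = train_control(epochs = 1, batch_size = 4))
  expect_output(print(fit), "deeplabv3plus")
  expect_output(summary(fit), "Per-epoch")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  tile <- ds$test_tiles[[1]]
  pm <- predict(fit, tile)
  expect_s3_class(pm, "probability_map")
  mk <- predict(fit, tile$model_image, type = "mask")
  expect_true(all(mk$values %in% c(0L, 1L)))
  sc <- generate_scene(small_params(seed = 77))
  mp <- predict(fit, sc$image)
  expect_s3_class(mp, "mosaic_prediction")
  expect_equal(dim(mp$full_mask$values), dim(sc$mask$values))
})
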