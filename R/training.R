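# Training: pixel-wise binary cross-entropy, Adam, and checkpointing of the
# best-validation-IoU epoch.

#' Training control parameters
#'
#' @param epochs Number of passes over the augmented training tiles.
#' @param batch_size Tiles per gradient step.
#' @param learning_rate Adam step size.
#' @param seed Seed for data shuffling (weight initialisation is seeded by
#'   the model spec).
#' @param threshold Binarisation threshold used for validation IoU.
#' @param early_stop_patience Stop after this many epochs without a
#'   validation-IoU improvement (`NULL` disables early stopping).
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 50L, batch_size = 16L,
                          learning_rate = 1e-3, seed = 1L, threshold = 0.5,
                          early_stop_patience = NULL) {
  if (!is_count(epochs) || !is_count(batch_size))
    stopf("epochs and batch_size must be integers >= 1")
  if (!is_number(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 threshold = threshold,
                 early_stop_patience = early_stop_patience),
            class = "train_control")
}

#' Mean pixel-wise binary cross-entropy
#'
#' Probabilities are clipped to `[eps, 1 - eps]` before taking logs, so the
#' loss is finite and bounded by `-log(eps)`.
#'
#' @param prob Probability map (`probability_map`, matrix or vector).
#' @param mask Aligned binary mask (`binary_mask`, matrix or vector).
#' @param eps Clipping constant (default `1e-7`).
#' @return Non-negative scalar: `mean(-(y log p + (1 - y) log(1 - p)))`.
#' @examples
#' pixel_cross_entropy(matrix(0.5, 2, 2), matrix(c(0, 1, 0, 1), 2))  # log(2)
#' @export
pixel_cross_entropy <- function(prob, mask, eps = 1e-7) {
  p <- raster_values(prob)
  y <- raster_values(mask)
  if (length(p) != length(y) ||
      (is.matrix(p) && is.matrix(y) && !all(dim(p) == dim(y))))
    stopf("probability map and mask shapes differ")
  check_binary_values(y)
  p <- clamp(as.numeric(p), eps, 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# One forward/backward pass on a tile; returns loss and parameter grads
# scaled by `scale` (1/batch size).
tile_grad <- function(model, tile, scale) {
  a <- tile_input(tile$model_image)
  y <- as.numeric(tile$model_mask)
  H <- dim(tile$model_image)[1]; W <- dim(tile$model_image)[2]
  fw <- model_logits(model, a, H, W)
  z <- fw$tape$vals[[fw$out$id]]
  p <- plogis(as.numeric(z))
  loss <- pixel_cross_entropy(p, y)
  dz <- matrix((p - y) / length(y) * scale, nrow = length(y), ncol = 1)
  list(loss = loss, grads = tape_backward(fw$tape, fw$out$id, dz))
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

#' Evaluate a model on a list of tiles
#'
#' @param model A `seg_model` or `seg_fit`.
#' @param tiles List of `tile_record`s with model-resolution rasters.
#' @param threshold Binarisation threshold.
#' @return A list with `mean_iou`, `mean_loss` and a per-tile data frame
#'   (`iou`, predicted and true foreground counts).
#' @export
evaluate_tiles <- function(model, tiles, threshold = 0.5) {
  if (inherits(model, "seg_fit")) model <- model$model
  if (!length(tiles)) stopf("no tiles to evaluate")
  rows <- lapply(tiles, function(t) {
    pm <- predict_map(model, t$model_image)
    pred <- binarize(pm, threshold)
    data.frame(parent_id = t$parent_id, quadrant = t$quadrant_index,
               iou = iou(pred, t$model_mask),
               loss = pixel_cross_entropy(pm, t$model_mask),
               pred_px = count_foreground(pred),
               true_px = sum(t$model_mask))
  })
  df <- do.call(rbind, rows)
  list(mean_iou = mean(df$iou), mean_loss = mean(df$loss), per_tile = df)
}

#' Fit a segmentation network to a tiled dataset
#'
#' Trains with pixel-wise binary cross-entropy and the Adam optimiser, and
#' returns the weights of the epoch with the best validation IoU (validation
#' loss breaks ties), not the last epoch.  Fully seeded: weight
#' initialisation by `spec$seed`, shuffling by `control$seed`; two runs with
#' identical seeds produce identical histories.
#'
#' @param data A `dataset_split` from [build_dataset()] with non-empty
#'   training and validation tile lists.
#' @param architecture Shorthand used when `spec` is `NULL`.
#' @param spec A [seg_model_spec()]; its `input_size` must match the
#'   dataset's `model_size`.
#' @param control A [train_control()].
#' @param model Optionally a pre-built `seg_model` to continue training.
#' @param quiet Suppress the per-epoch progress line.
#' @return An object of class `seg_fit`: the checkpointed `model`, a
#'   `train_history` (per-epoch train loss, validation loss and IoU,
#'   `best_epoch`, `best_val_iou`), the control and the dataset accounting.
#'   Methods: [print.seg_fit()], [summary.seg_fit()], [predict.seg_fit()],
#'   [plot.seg_fit()].
#' @export
fit_segmenter <- function(data, architecture = c("unet", "deeplabv3plus",
                                                 "unet_xception"),
                          spec = NULL, control = train_control(),
                          model = NULL, quiet = TRUE) {
  if (!inherits(data, "dataset_split"))
    stopf("data must be a dataset_split from build_dataset()")
  if (!length(data$train_tiles)) stopf("training set is empty")
  if (!length(data$validation_tiles))
    stopf("validation set is empty; checkpoint selection needs one (set val_fraction > 0)")
  if (is.null(model)) {
    if (is.null(spec))
      spec <- seg_model_spec(match.arg(architecture),
                             input_size = data$model_size)
    model <- build_seg_model(spec)
  }
  spec <- model$spec
  if (spec$input_size != data$model_size)
    stopf("spec input_size (%d) != dataset model_size (%d)",
          spec$input_size, data$model_size)

  n <- length(data$train_tiles)
  hist_rows <- vector("list", control$epochs)
  best <- list(iou = -Inf, loss = Inf, epoch = NA_integer_, params = NULL)
  with_seed(control$seed, {
    st <- adam_new(model$params)
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      done <- 0L
      while (done < n) {
        take <- ord[(done + 1L):min(n, done + control$batch_size)]
        gacc <- NULL
        for (ti in take) {
          r <- tile_grad(model, data$train_tiles[[ti]], 1 / length(take))
          ep_loss <- ep_loss + r$loss
          gacc <- if (is.null(gacc)) r$grads
                  else Map(`+`, gacc, r$grads[names(gacc)])
        }
        upd <- adam_step(model$params, gacc, st, control$learning_rate)
        model$params <- upd$params
        st <- upd$state
        done <- done + length(take)
      }
      ev <- evaluate_tiles(model, data$validation_tiles, control$threshold)
      hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n,
                                    val_loss = ev$mean_loss,
                                    val_iou = ev$mean_iou)
      if (!quiet)
        message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val IoU %.4f",
                        ep, ep_loss / n, ev$mean_loss, ev$mean_iou))
      if (ev$mean_iou > best$iou ||
          (ev$mean_iou == best$iou && ev$mean_loss < best$loss)) {
        best <- list(iou = ev$mean_iou, loss = ev$mean_loss, epoch = ep,
                     params = model$params)
      }
      if (!is.null(control$early_stop_patience) &&
          ep - best$epoch >= control$early_stop_patience) break
    }
  })
  model$params <- best$params
  metrics <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1))])
  history <- structure(list(metrics = metrics, best_epoch = best$epoch,
                            best_val_iou = best$iou),
                       class = "train_history")
  structure(list(model = model, history = history, control = control,
                 accounting = data$accounting, call = match.call()),
            class = "seg_fit")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs; best validation IoU %.4f at epoch %d\n",
              nrow(x$metrics), x$best_val_iou, x$best_epoch))
  invisible(x)
}

#' @export
print.seg_fit <- function(x, ...) {
  s <- x$model$spec
  cat(sprintf("Segmentation fit: %s (base_filters %d, depth %d, input %dx%d)\n",
              s$architecture, s$base_filters, s$depth, s$input_size,
              s$input_size))
  cat(sprintf("  parameters: %s\n", format(n_params(x), big.mark = ",")))
  cat(sprintf("  epochs run: %d; checkpoint: epoch %d (validation IoU %.4f)\n",
              nrow(x$history$metrics), x$history$best_epoch,
              x$history$best_val_iou))
  invisible(x)
}

#' Summary of a segmentation fit
#' @param object A `seg_fit`.
#' @param ... Unused.
#' @export
summary.seg_fit <- function(object, ...) {
  print(object)
  cat("\nPer-epoch metrics:\n")
  print(object$history$metrics, row.names = FALSE, digits = 4)
  invisible(object$history$metrics)
}

#' Predict from a segmentation fit
#'
#' @param object A `seg_fit`.
#' @param newdata Either a model-resolution `H x W x 3` array (or
#'   `tile_record`), which yields a probability map or binary mask, or an
#'   [ortho_image], which is segmented tile-wise at full resolution via
#'   [segment_orthomosaic()].
#' @param type `"prob"` or `"mask"` for tiles; ignored for orthomosaics.
#' @param threshold Binarisation threshold.
#' @param ... Unused.
#' @export
predict.seg_fit <- function(object, newdata, type = c("prob", "mask"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ortho_image"))
    return(segment_orthomosaic(object$model, newdata, threshold = threshold))
  if (inherits(newdata, "tile_record")) newdata <- newdata$model_image
  pm <- predict_map(object$model, newdata)
  if (type == "prob") pm else binarize(pm, threshold)
}

#' Plot training curves
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @export
plot.seg_fit <- function(x, ...) {
  m <- x$history$metrics
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(m$epoch, m$train_loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "cross-entropy", main = "loss",
       ylim = range(c(m$train_loss, m$val_loss)))
  lines(m$epoch, m$val_loss, type = "b", pch = 1, lty = 2)
  legend("topright", c("train", "validation"), pch = c(16, 1),
         lty = c(1, 2), bty = "n")
  plot(m$epoch, m$val_iou, type = "b", pch = 16, xlab = "epoch",
       ylab = "IoU", main = "validation IoU", ylim = c(0, 1))
  invisible(x)
}
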