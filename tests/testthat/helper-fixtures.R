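# Shared fixtures: everything is generated in code at test time.

# A small, quick field scene.
small_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(width_px = 200L, height_px = 180L,
                                 n_rows = 2L, plants_per_row = 3L,
                                 seed = seed),
                            list(...))
  do.call(scene_params, args)
}

# Random binary mask of given size.
rand_mask <- function(h, w, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Random 8-bit image array.
rand_image <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.integer(runif(h * w * 3, 0, 256) %% 256), dim = c(h, w, 3L))
}

# Tiny architecture spec for fast forward/backward runs.
tiny_spec <- function(arch, input_size = 32L, seed = 1L, ...) {
  seg_model_spec(arch, input_size = input_size, base_filters = 4L,
                 depth = 2L, atrous_rates = c(1L, 2L), seed = seed, ...)
}

# A synthetic mock survey raster at arbitrary size: flat soil-coloured image
# with one vegetation rectangle; cheap enough for full 4000 x 2250 builds.
mock_scene <- function(h, w, id, fg_frac = 0.15) {
  img <- array(110L, dim = c(h, w, 3L))
  mk <- matrix(0L, h, w)
  rh <- max(1L, as.integer(round(h * sqrt(fg_frac))))
  rw <- max(1L, as.integer(round(w * sqrt(fg_frac))))
  i0 <- as.integer((h - rh) / 2) + 1L; j0 <- as.integer((w - rw) / 2) + 1L
  mk[i0:(i0 + rh - 1L), j0:(j0 + rw - 1L)] <- 1L
  list(image = ortho_image(img, id = id), mask = binary_mask(mk, id = id))
}

# Independent brute-force IoU: per-pixel set evaluation with explicit loops.
brute_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a))) {
      if (a[i, j] == 1L && b[i, j] == 1L) inter <- inter + 1L
      if (a[i, j] == 1L || b[i, j] == 1L) uni <- uni + 1L
    }
  if (uni == 0L) 1.0 else inter / uni
}

# Independent brute-force RMSE.
brute_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}
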