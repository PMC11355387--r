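test_that("spec validation enforces divisibility and positivity", {
  expect_error(seg_model_spec("unet", input_size = 100, depth = 3),
               "divisible")
  expect_error(seg_model_spec("unet", base_filters = 0), "positive")
  expect_error(seg_model_spec("deeplabv3plus", atrous_rates = c(0, 2)),
               "positive")
  expect_error(seg_model_spec("resnet"), "arg")
})

test_that("every architecture satisfies the shape/range contract", {
  img <- rand_image(32, 32, seed = 1)
  for (arch in c("unet", "deeplabv3plus", "unet_xception")) {
    model <- build_seg_model(tiny_spec(arch))
    pm <- predict_map(model, img)
    expect_equal(dim(pm$values), c(32L, 32L))
    expect_true(all(pm$values >= 0 & pm$values <= 1))
    # inference determinism
    pm2 <- predict_map(model, img)
    expect_identical(pm$values, pm2$values)
    # wrong input size is rejected, not silently resized
    expect_error(predict_map(model, rand_image(16, 16)), "expected")
  }
})

test_that("initialisation is reproducible from the spec seed", {
  for (arch in c("unet", "deeplabv3plus", "unet_xception")) {
    m1 <- build_seg_model(tiny_spec(arch, seed = 7))
    m2 <- build_seg_model(tiny_spec(arch, seed = 7))
    expect_identical(m1$params, m2$params)
    m3 <- build_seg_model(tiny_spec(arch, seed = 8))
    expect_false(identical(m1$params, m3$params))
  }
})

test_that("UNet parameter count matches the hand-summed layer arithmetic", {
  model <- build_seg_model(seg_model_spec("unet", input_size = 32,
                                          base_filters = 2, depth = 1))
  # encoder: 3x3x3->2 and 3x3x2->2; bottleneck: 2->4, 4->4;
  # up-convolution 2x2: 4->2; decoder convs on concat(2+2): 4->2, 2->2;
  # head 1x1: 2->1.  Each conv adds cout biases.
  hand <- (3 * 3 * 3 * 2 + 2) + (3 * 3 * 2 * 2 + 2) +
    (3 * 3 * 2 * 4 + 4) + (3 * 3 * 4 * 4 + 4) +
    (2 * 2 * 4 * 2 + 2) +
    (3 * 3 * 4 * 2 + 2) + (3 * 3 * 2 * 2 + 2) +
    (1 * 1 * 2 * 1 + 1)
  expect_equal(n_params(model), hand)
})

test_that("separable blocks are strictly lighter than standard blocks", {
  bf <- 8L
  std <- build_seg_model(seg_model_spec("unet", input_size = 32,
                                        base_filters = bf, depth = 2))
  sep <- build_seg_model(seg_model_spec("unet_xception", input_size = 32,
                                        base_filters = bf, depth = 2))
  block_params <- function(model, prefix)
    sum(vapply(model$params[grepl(paste0("^", prefix), names(model$params))],
               length, numeric(1)))
  for (blk in c("enc1", "enc2", "bot"))
    expect_lt(block_params(sep, blk), block_params(std, blk))
})

test_that("a zeroed sigmoid head predicts exactly 0.5 everywhere", {
  for (arch in c("unet", "deeplabv3plus", "unet_xception")) {
    model <- build_seg_model(tiny_spec(arch))
    model$params[["head.w"]][] <- 0
    model$params[["head.b"]][] <- 0
    pm <- predict_map(model, rand_image(32, 32, seed = 2))
    expect_true(all(pm$values == 0.5))
  }
})

test_that("a rate-r dilated 3x3 kernel has receptive field 2r+1 per side", {
  for (r in c(1L, 3L)) {
    h <- 31L
    x <- matrix(0, h * h, 1)
    x[(h * h + 1) / 2, 1] <- 1           # unit impulse at the centre
    w <- matrix(1, 9, 1)
    y <- opuntiaseg:::nn_conv_fwd(x, h, h, w, 0, 3L, 1L, r)$y
    support <- matrix(y != 0, h, h)
    rows <- which(rowSums(support) > 0)
    cols <- which(colSums(support) > 0)
    expect_equal(diff(range(rows)) + 1L, 2L * r + 1L)
    expect_equal(diff(range(cols)) + 1L, 2L * r + 1L)
  }
})

test_that("convolutional pipelines are translation invariant on constant input", {
  model <- build_seg_model(tiny_spec("deeplabv3plus"))
  const_img <- array(0L, dim = c(32L, 32L, 3L))
  pm <- predict_map(model, const_img)
  expect_lt(max(pm$values) - min(pm$values), 1e-5)
})

test_that("a degenerate single-rate pyramid still meets the contract", {
  spec <- seg_model_spec("deeplabv3plus", input_size = 32, base_filters = 4,
                         depth = 2, atrous_rates = 1L)
  pm <- predict_map(build_seg_model(spec), rand_image(32, 32, seed = 3))
  expect_equal(dim(pm$values), c(32L, 32L))
  expect_true(all(pm$values >= 0 & pm$values <= 1))
})

test_that("batched prediction equals per-image prediction", {
  model <- build_seg_model(tiny_spec("unet"))
  imgs <- lapply(1:3, function(i) rand_image(32, 32, seed = 10 + i))
  batch <- lapply(imgs, function(im) predict_map(model, im)$values)
  single <- lapply(imgs, function(im) predict_map(model, im)$values)
  for (i in 1:3) expect_lt(max(abs(batch[[i]] - single[[i]])), 1e-5)
})

test_that("analytic layer gradients match central differences", {
  ns <- asNamespace("opuntiaseg")
  set.seed(33)
  H <- 6L; W <- 6L; C <- 3L; cout <- 4L
  x0 <- matrix(rnorm(H * W * C), H * W, C)
  eps <- 5e-2
  gc1 <- function(fwd, x0, dx) {
    worst <- 0
    for (idx in sample(length(x0), min(10, length(x0)))) {
      xp <- x0; xp[idx] <- xp[idx] + eps
      xm <- x0; xm[idx] <- xm[idx] - eps
      num <- (fwd(xp) - fwd(xm)) / (2 * eps)
      worst <- max(worst, abs(num - dx[idx]) /
                     max(1e-4, abs(num) + abs(dx[idx])))
    }
    worst
  }
  wt <- matrix(rnorm(9 * C * cout), 9 * C, cout); bb <- rnorm(cout)
  for (cfg in list(c(1L, 1L), c(2L, 1L), c(1L, 2L))) {
    r <- ns$nn_conv_fwd(x0, H, W, wt, bb, 3L, cfg[1], cfg[2])
    pr <- matrix(rnorm(r$H * r$W * cout), ncol = cout)
    bw <- ns$nn_conv_bwd(x0, H, W, wt, pr, 3L, cfg[1], cfg[2])
    expect_lt(gc1(function(x)
      sum(ns$nn_conv_fwd(x, H, W, wt, bb, 3L, cfg[1], cfg[2])$y * pr),
      x0, bw$dx), 5e-3)
    expect_lt(gc1(function(w)
      sum(ns$nn_conv_fwd(x0, H, W, w, bb, 3L, cfg[1], cfg[2])$y * pr),
      wt, bw$dw), 5e-3)
  }
  wct <- matrix(rnorm(C * 4 * cout), C, 4 * cout)
  r <- ns$nn_convt_fwd(x0, H, W, wct, bb)
  pr <- matrix(rnorm(r$H * r$W * cout), ncol = cout)
  bw <- ns$nn_convt_bwd(x0, H, W, wct, pr)
  expect_lt(gc1(function(x) sum(ns$nn_convt_fwd(x, H, W, wct, bb)$y * pr),
                x0, bw$dx), 5e-3)
  expect_lt(gc1(function(w) sum(ns$nn_convt_fwd(x0, H, W, w, bb)$y * pr),
                wct, bw$dw), 5e-3)
  wd <- matrix(rnorm(9 * C), 9, C); bd <- rnorm(C)
  r <- ns$nn_dwconv_fwd(x0, H, W, wd, bd, 3L, 1L)
  pr <- matrix(rnorm(H * W * C), ncol = C)
  bw <- ns$nn_dwconv_bwd(x0, H, W, wd, pr, 3L, 1L)
  expect_lt(gc1(function(x) sum(ns$nn_dwconv_fwd(x, H, W, wd, bd, 3L, 1L)$y * pr),
                x0, bw$dx), 5e-3)
  expect_lt(gc1(function(w) sum(ns$nn_dwconv_fwd(x0, H, W, w, bd, 3L, 1L)$y * pr),
                wd, bw$dw), 5e-3)
  r <- ns$nn_maxpool_fwd(x0, H, W)
  pr <- matrix(rnorm(r$H * r$W * C), ncol = C)
  dx <- ns$nn_maxpool_bwd(pr, r$idx, H, W)
  expect_lt(gc1(function(x) {
    rr <- ns$nn_maxpool_fwd(x, H, W)
    sum(rr$y * pr)
  }, x0, dx), 1e-2)    # kinks at pooling ties
  pr <- matrix(rnorm(12 * 18 * C), ncol = C)
  dx <- ns$nn_upsample_bwd(pr, H, W, 12L, 18L)
  expect_lt(gc1(function(x)
    sum(ns$nn_upsample_fwd(x, H, W, 12L, 18L) * pr), x0, dx), 5e-3)
})
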