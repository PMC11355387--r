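# The three segmentation architectures behind one interface.
#
# All three map an input_size x input_size x 3 image to a per-pixel
# vegetation probability map of the same spatial size: a classic UNet
# (double 3x3 convolution blocks, 2x2 max pooling, 2x2 up-convolutions with
# skip concatenations), a compact DeepLabV3+ (strided-convolution backbone,
# atrous spatial pyramid with an image-level pooling branch, low-level skip
# decoder), and a UNet in the Xception style (depthwise-separable
# convolutions with residual shortcut projections).  'Same' padding is used
# throughout so the output grid equals the input grid, and the binary task
# ends in a single-channel sigmoid head.

#' Specification of a segmentation network
#'
#' @param architecture `"unet"`, `"deeplabv3plus"` or `"unet_xception"`.
#' @param input_size Square input resolution; must be divisible by
#'   `2^depth`.  Default 160.
#' @param base_filters Channels of the first encoder stage; doubled at each
#'   deeper stage.  Default 32.
#' @param depth Number of encoder stages (resolution halvings).  Default 4.
#' @param atrous_rates Dilation rates of the atrous pyramid
#'   (DeepLabV3+ only).
#' @param seed Seed for weight initialisation.
#' @return An object of class `seg_model_spec`.
#' @export
seg_model_spec <- function(architecture = c("unet", "deeplabv3plus",
                                            "unet_xception"),
                           input_size = 160L, base_filters = 32L,
                           depth = 4L, atrous_rates = c(1L, 6L, 12L, 18L),
                           seed = 1L) {
  architecture <- match.arg(architecture)
  if (!is_count(input_size, 8) || !is_count(base_filters) || !is_count(depth))
    stopf("input_size, base_filters and depth must be positive integers")
  if (input_size %% (2^depth) != 0)
    stopf("input_size (%d) must be divisible by 2^depth (%d)",
          input_size, 2^depth)
  if (any(atrous_rates < 1) || !length(atrous_rates))
    stopf("atrous_rates must be strictly positive")
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 atrous_rates = as.integer(atrous_rates),
                 seed = as.integer(seed)),
            class = "seg_model_spec")
}

unet_params <- function(spec) {
  bf <- spec$base_filters; d <- spec$depth
  p <- list(); cin <- 3L
  for (i in seq_len(d)) {
    f <- bf * 2^(i - 1)
    p <- add_param(p, sprintf("enc%d_c1", i), init_conv(3, cin, f))
    p <- add_param(p, sprintf("enc%d_c2", i), init_conv(3, f, f))
    cin <- f
  }
  fb <- bf * 2^d
  p <- add_param(p, "bot_c1", init_conv(3, cin, fb))
  p <- add_param(p, "bot_c2", init_conv(3, fb, fb))
  cur <- fb
  for (i in rev(seq_len(d))) {
    f <- bf * 2^(i - 1)
    p <- add_param(p, sprintf("dec%d_up", i), init_convt(cur, f))
    p <- add_param(p, sprintf("dec%d_c1", i), init_conv(3, 2 * f, f))
    p <- add_param(p, sprintf("dec%d_c2", i), init_conv(3, f, f))
    cur <- f
  }
  add_param(p, "head", init_conv(1, cur, 1, gain = 1))
}

unet_forward <- function(tp, spec, x) {
  d <- spec$depth
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    x <- op_conv(tp, sprintf("enc%d_c1", i), x, 3)
    x <- op_conv(tp, sprintf("enc%d_c2", i), x, 3)
    skips[[i]] <- x
    x <- op_pool(tp, x)
  }
  x <- op_conv(tp, "bot_c1", x, 3)
  x <- op_conv(tp, "bot_c2", x, 3)
  for (i in rev(seq_len(d))) {
    x <- op_convt(tp, sprintf("dec%d_up", i), x)
    x <- op_concat(tp, x, skips[[i]])
    x <- op_conv(tp, sprintf("dec%d_c1", i), x, 3)
    x <- op_conv(tp, sprintf("dec%d_c2", i), x, 3)
  }
  op_conv(tp, "head", x, 1, act = "linear")
}

xcep_block_params <- function(p, name, cin, f) {
  p <- add_param(p, paste0(name, "_dw1"), init_dwconv(3, cin))
  p <- add_param(p, paste0(name, "_pw1"), init_conv(1, cin, f))
  p <- add_param(p, paste0(name, "_dw2"), init_dwconv(3, f))
  p <- add_param(p, paste0(name, "_pw2"), init_conv(1, f, f))
  add_param(p, paste0(name, "_sc"), init_conv(1, cin, f))
}

xcep_block_forward <- function(tp, name, x) {
  m <- op_dwconv(tp, paste0(name, "_dw1"), x)
  m <- op_conv(tp, paste0(name, "_pw1"), m, 1)
  m <- op_dwconv(tp, paste0(name, "_dw2"), m)
  m <- op_conv(tp, paste0(name, "_pw2"), m, 1, act = "linear")
  s <- op_conv(tp, paste0(name, "_sc"), x, 1, act = "linear")
  op_relu(tp, op_add(tp, m, s))
}

xcep_params <- function(spec) {
  bf <- spec$base_filters; d <- spec$depth
  p <- list(); cin <- 3L
  for (i in seq_len(d)) {
    f <- bf * 2^(i - 1)
    p <- xcep_block_params(p, sprintf("enc%d", i), cin, f)
    cin <- f
  }
  fb <- bf * 2^d
  p <- xcep_block_params(p, "bot", cin, fb)
  cur <- fb
  for (i in rev(seq_len(d))) {
    f <- bf * 2^(i - 1)
    p <- add_param(p, sprintf("dec%d_up", i), init_convt(cur, f))
    p <- xcep_block_params(p, sprintf("dec%d", i), 2 * f, f)
    cur <- f
  }
  add_param(p, "head", init_conv(1, cur, 1, gain = 1))
}

xcep_forward <- function(tp, spec, x) {
  d <- spec$depth
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    x <- xcep_block_forward(tp, sprintf("enc%d", i), x)
    skips[[i]] <- x
    x <- op_pool(tp, x)
  }
  x <- xcep_block_forward(tp, "bot", x)
  for (i in rev(seq_len(d))) {
    x <- op_convt(tp, sprintf("dec%d_up", i), x)
    x <- op_concat(tp, x, skips[[i]])
    x <- xcep_block_forward(tp, sprintf("dec%d", i), x)
  }
  op_conv(tp, "head", x, 1, act = "linear")
}

deeplab_params <- function(spec) {
  bf <- spec$base_filters; d <- spec$depth
  p <- list(); cin <- 3L
  for (i in seq_len(d)) {
    f <- bf * 2^(i - 1)
    p <- add_param(p, sprintf("stage%d_c1", i), init_conv(3, cin, f))
    p <- add_param(p, sprintf("stage%d_c2", i), init_conv(3, f, f))
    cin <- f
  }
  fa <- bf * 2^(d - 1)
  for (j in seq_along(spec$atrous_rates))
    p <- add_param(p, sprintf("aspp_r%d", j), init_conv(3, cin, fa))
  p <- add_param(p, "aspp_pool", init_conv(1, cin, fa))
  p <- add_param(p, "aspp_proj",
                 init_conv(1, (length(spec$atrous_rates) + 1L) * fa, fa))
  p <- add_param(p, "low_proj", init_conv(1, bf, bf))
  fd <- max(bf, fa %/% 2)
  p <- add_param(p, "dec_c1", init_conv(3, fa + bf, fd))
  p <- add_param(p, "dec_c2", init_conv(3, fd, fd))
  add_param(p, "head", init_conv(1, fd, 1, gain = 1))
}

deeplab_forward <- function(tp, spec, x) {
  d <- spec$depth
  H <- x$H; W <- x$W
  low <- NULL
  for (i in seq_len(d)) {
    x <- op_conv(tp, sprintf("stage%d_c1", i), x, 3, stride = 2)
    x <- op_conv(tp, sprintf("stage%d_c2", i), x, 3)
    if (i == 1L) low <- x
  }
  branches <- lapply(seq_along(spec$atrous_rates), function(j)
    op_conv(tp, sprintf("aspp_r%d", j), x, 3, dil = spec$atrous_rates[j]))
  pool <- op_gap(tp, x)
  pool <- op_conv(tp, "aspp_pool", pool, 1)
  pool <- op_broadcast(tp, pool, x$H, x$W)
  a <- branches[[1]]
  for (b in branches[-1]) a <- op_concat(tp, a, b)
  a <- op_concat(tp, a, pool)
  a <- op_conv(tp, "aspp_proj", a, 1)
  a <- op_up(tp, a, low$H, low$W)
  lowp <- op_conv(tp, "low_proj", low, 1)
  a <- op_concat(tp, a, lowp)
  a <- op_conv(tp, "dec_c1", a, 3)
  a <- op_conv(tp, "dec_c2", a, 3)
  a <- op_up(tp, a, H, W)
  op_conv(tp, "head", a, 1, act = "linear")
}

arch_funs <- function(architecture) {
  switch(architecture,
         unet = list(params = unet_params, forward = unet_forward),
         deeplabv3plus = list(params = deeplab_params,
                              forward = deeplab_forward),
         unet_xception = list(params = xcep_params, forward = xcep_forward),
         stopf("unknown architecture '%s'", architecture))
}

#' Build a segmentation model from a specification
#'
#' Initialises the network weights (He-style, seeded by `spec$seed`; two
#' builds from the same spec are bit-identical).
#'
#' @param spec A [seg_model_spec()].
#' @return An object of class `seg_model` with elements `spec`, `params`
#'   (named list of weight matrices and bias vectors) and `id`.
#' @export
build_seg_model <- function(spec) {
  if (!inherits(spec, "seg_model_spec"))
    stopf("spec must be created by seg_model_spec()")
  fns <- arch_funs(spec$architecture)
  params <- with_seed(spec$seed, fns$params(spec))
  structure(list(spec = spec, params = params,
                 id = sprintf("%s_f%d_d%d", spec$architecture,
                              spec$base_filters, spec$depth)),
            class = "seg_model")
}

#' Number of trainable parameters
#' @param model A `seg_model` or `seg_fit`.
#' @return Integer count of weights and biases.
#' @export
n_params <- function(model) {
  if (inherits(model, "seg_fit")) model <- model$model
  sum(vapply(model$params, length, numeric(1)))
}

# Forward pass to the logit layer; input a (H*W) x 3 matrix in [0, 1].
model_logits <- function(model, a, H, W) {
  tp <- tape_new(model$params)
  x <- op_input(tp, a, H, W)
  out <- arch_funs(model$spec$architecture)$forward(tp, model$spec, x)
  list(tape = tp, out = out)
}

tile_input <- function(img) {
  d <- dim(img)
  m <- matrix(as.numeric(img), d[1] * d[2], d[3])
  if (max(m) > 1) m <- m / 255
  m
}

#' Per-pixel vegetation probabilities for one model-resolution image
#'
#' Deterministic inference: the image must already be at the model's input
#' resolution (rescaling belongs to the dataset/tiling stage) with
#' intensities in `[0, 1]` (8-bit inputs are rescaled by 255).
#'
#' @param model A `seg_model` or `seg_fit`.
#' @param image `H x W x 3` array with `H = W = input_size`.
#' @return An object of class `probability_map`: `values` (`H x W` matrix in
#'   `[0, 1]`) and the source `model_id`.
#' @export
predict_map <- function(model, image) {
  if (inherits(model, "seg_fit")) model <- model$model
  d <- dim(image)
  s <- model$spec$input_size
  if (length(d) != 3L || d[1] != s || d[2] != s || d[3] != 3L)
    stopf("expected a %d x %d x 3 input, got %s", s, s,
          paste(d, collapse = " x "))
  fw <- model_logits(model, tile_input(image), d[1], d[2])
  structure(list(values = matrix(plogis(fw$tape$vals[[fw$out$id]]), d[1], d[2]),
                 model_id = model$id),
            class = "probability_map")
}
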