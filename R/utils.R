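# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded operations do not perturb the global stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce the various raster spellings used around the package.
raster_values <- function(x) {
  if (inherits(x, "ortho_image")) x$pixels
  else if (inherits(x, "binary_mask")) x$values
  else if (inherits(x, "probability_map")) x$values
  else x
}

raster_id <- function(x, default = "raster") {
  if (inherits(x, c("ortho_image", "binary_mask", "probability_map")) &&
      !is.null(x$id)) x$id else default
}

check_binary_values <- function(v, what = "mask") {
  if (!all(v %in% c(0, 1)))
    stopf("%s must contain only 0/1 values", what)
  invisible(TRUE)
}

# Rotations and flips used for augmentation; exact integer index operations.
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
hflip <- function(m) m[, ncol(m):1, drop = FALSE]

apply_planes <- function(x, f) {
  if (length(dim(x)) == 2L) return(f(x))
  planes <- lapply(seq_len(dim(x)[3]), function(k) f(x[, , k]))
  array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
}

# EBImage-backed resampling.  EBImage maps `w`/`h` onto the first/second array
# dimension, which matches the row/column convention used here; the third
# (channel) dimension is untouched.
resize_raster <- function(x, th, tw, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(x), w = th, h = tw,
                                            filter = filt))
  dim(out) <- if (length(dim(x)) == 2L) c(th, tw) else c(th, tw, dim(x)[3])
  out
}
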