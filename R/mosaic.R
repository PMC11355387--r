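# Full-mosaic inference: quadrant tiling, per-tile prediction, binarisation,
# nearest-neighbour upscaling back to native resolution, seam-free
# reassembly, and the blue overlay.

#' Binarise a probability map
#'
#' A pixel is foreground iff its probability is greater than or equal to the
#' threshold (ties map to foreground).
#'
#' @param prob A `probability_map` or numeric matrix in `[0, 1]`.
#' @param threshold Cut-off strictly inside (0, 1).
#' @return A [binary_mask].
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (!is_number(threshold) || threshold <= 0 || threshold >= 1)
    stopf("threshold must be strictly inside (0, 1)")
  v <- raster_values(prob)
  m <- matrix(as.integer(v >= threshold), nrow(v), ncol(v))
  binary_mask(m, id = raster_id(prob))
}

#' Upscale a binary mask to native resolution
#'
#' Nearest-neighbour resampling, so the result is strictly binary and
#' constant masks stay constant.
#'
#' @param mask A [binary_mask] or 0/1 matrix at model resolution.
#' @param target_h,target_w Target dimensions; must not be below the source
#'   dimensions.
#' @return A [binary_mask] of size `target_h x target_w`.
#' @export
upscale_mask <- function(mask, target_h, target_w) {
  v <- raster_values(mask)
  check_binary_values(v)
  if (target_h < nrow(v) || target_w < ncol(v))
    stopf("target dimensions (%d x %d) below source (%d x %d)",
          target_h, target_w, nrow(v), ncol(v))
  out <- resize_raster(v, target_h, target_w, bilinear = FALSE)
  storage.mode(out) <- "integer"
  binary_mask(out, id = raster_id(mask))
}

#' Segment a full orthomosaic by tiled inference
#'
#' The mosaic-scale pipeline: split the orthophoto into quadrants (recursing
#' while a quadrant exceeds `max_tile`, so mosaics of any size reduce to
#' network-sized tiles), rescale each tile to the model input size, predict,
#' binarise, upscale each tile mask back to its native size
#' (nearest-neighbour), and reassemble a seam-free full-resolution mask.
#'
#' @param model A `seg_model`/`seg_fit`, or a function `f(tile_record)`
#'   returning an `input_size x input_size` probability matrix -- the latter
#'   admits oracle "models" for quantifying the tiling/rescale quantisation
#'   error in isolation.
#' @param image An [ortho_image] (at least 2 x 2).
#' @param threshold Binarisation threshold.
#' @param input_size Model input resolution; taken from the model spec when
#'   available.
#' @param max_tile `c(height, width)`: largest tile processed directly
#'   (default 2000 x 1125, one split of a 4000 x 2250 survey image).
#' @return An object of class `mosaic_prediction`: `full_mask` (a
#'   [binary_mask] with the mosaic's exact dimensions), `tile_probs` (per-
#'   tile probability maps with offsets), `threshold`, `model_id`.
#' @export
segment_orthomosaic <- function(model, image, threshold = 0.5,
                                input_size = NULL, max_tile = c(2000L, 1125L)) {
  if (inherits(model, "seg_fit")) model <- model$model
  if (inherits(model, "seg_model") && is.null(input_size))
    input_size <- model$spec$input_size
  if (is.null(input_size)) input_size <- 160L
  px <- raster_values(image)
  if (nrow(px) < 2L || ncol(px) < 2L) stopf("image must be at least 2 x 2")

  predict_tile <- function(tile) {
    if (is.function(model)) {
      pv <- raster_values(model(tile))
    } else {
      pv <- predict_map(model, tile$model_image)$values
    }
    pv
  }

  tile_probs <- list()
  recurse <- function(sub_img, id, row0, col0) {
    tiles <- split_into_quadrants(ortho_image(sub_img, image$pixel_area_m2,
                                              id = id))
    masks <- lapply(tiles, function(t) {
      h <- dim(t$native_image)[1]; w <- dim(t$native_image)[2]
      if (h > max_tile[1] || w > max_tile[2]) {
        sub <- recurse(t$native_image, t$parent_id,
                       row0 + t$row_offset, col0 + t$col_offset)
        t$native_mask <- sub
        t$native_image <- NULL
        return(t)
      }
      t <- resize_pair(t, input_size)
      t$abs_row_offset <- row0 + t$row_offset
      t$abs_col_offset <- col0 + t$col_offset
      pv <- predict_tile(t)
      tile_probs[[length(tile_probs) + 1L]] <<- list(
        row_offset = t$abs_row_offset, col_offset = t$abs_col_offset,
        native_h = h, native_w = w, values = pv)
      bm <- binarize(pv, threshold)
      t$native_mask <- upscale_mask(bm, h, w)$values
      t$native_image <- NULL
      t
    })
    reassemble_quadrants(masks)$mask
  }
  full <- recurse(px, raster_id(image), 0L, 0L)
  structure(list(full_mask = binary_mask(full, id = raster_id(image)),
                 tile_probs = tile_probs,
                 threshold = threshold,
                 model_id = if (is.function(model)) "oracle" else model$id),
            class = "mosaic_prediction")
}

#' @export
print.mosaic_prediction <- function(x, ...) {
  v <- x$full_mask$values
  cat(sprintf("Mosaic prediction (%s): %d x %d px, %d tiles, threshold %.2f\n",
              x$model_id, nrow(v), ncol(v), length(x$tile_probs),
              x$threshold))
  cat(sprintf("  vegetation: %d px (%.1f%% cover)\n", sum(v),
              100 * mean(v)))
  invisible(x)
}

#' Blue vegetation overlay
#'
#' Alpha-blends foreground pixels toward the given colour (default pure
#' blue); background pixels are bit-identical to the input.
#'
#' @param image An [ortho_image] or `H x W x 3` array.
#' @param mask Aligned [binary_mask] or 0/1 matrix.
#' @param color Overlay colour, length-3 vector in 0--255.
#' @param alpha Blend factor in `[0, 1]`; 1 paints foreground pixels with
#'   the pure colour.
#' @return `H x W x 3` integer array.
#' @export
overlay_mask <- function(image, mask, color = c(0L, 0L, 255L), alpha = 0.6) {
  px <- raster_values(image)
  mv <- raster_values(mask)
  if (!all(dim(px)[1:2] == dim(mv)))
    stopf("image and mask shapes differ")
  check_binary_values(mv)
  fg <- mv == 1L
  out <- px
  for (k in 1:3) {
    pl <- out[, , k]
    pl[fg] <- as.integer(round((1 - alpha) * pl[fg] + alpha * color[k]))
    out[, , k] <- pl
  }
  out
}
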