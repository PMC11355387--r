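# Vegetation quantification and validation metrics: pixel counting, area
# conversion, intersection-over-union, RMSE, and the per-model area report
# against a reference mask.

#' Count vegetation pixels in a binary mask
#' @param mask A [binary_mask] or 0/1 matrix.
#' @return Exact number of foreground (value 1) pixels.
#' @export
count_foreground <- function(mask) {
  v <- raster_values(mask)
  check_binary_values(v)
  sum(v == 1)
}

#' Convert a pixel count to ground area
#'
#' @param pixel_count Non-negative vegetation pixel count.
#' @param pixel_area_m2 Ground area of one pixel in m^2 (see
#'   [default_pixel_area()]).
#' @return Area in square metres: `pixel_count * pixel_area_m2`.
#' @examples
#' area_from_count(128959, default_pixel_area())  # 54.195 m^2
#' @export
area_from_count <- function(pixel_count, pixel_area_m2 = default_pixel_area()) {
  if (any(pixel_count < 0)) stopf("pixel_count must be non-negative")
  if (!is_number(pixel_area_m2) || pixel_area_m2 <= 0)
    stopf("pixel_area_m2 must be positive")
  pixel_count * pixel_area_m2
}

#' Intersection over union of two binary masks
#'
#' `|pred & ref| / (|ref| + |pred| - |pred & ref|)`.  Two empty masks agree
#' perfectly and score 1.
#'
#' @param pred,ref Aligned [binary_mask] objects or 0/1 matrices.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pred, ref) {
  p <- raster_values(pred)
  r <- raster_values(ref)
  if (!all(dim(p) == dim(r))) stopf("mask shapes differ")
  check_binary_values(p, "pred")
  check_binary_values(r, "ref")
  inter <- sum(p == 1 & r == 1)
  union <- sum(p == 1) + sum(r == 1) - inter
  if (union == 0) 1.0 else inter / union
}

#' Root mean square error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0)
    stopf("observed and predicted must be non-empty vectors of equal length")
  sqrt(mean((observed - predicted)^2))
}

# Per-quadrant foreground counts at native resolution (the observation
# units of the mosaic-level RMSE).
quadrant_counts <- function(mask) {
  tiles <- split_into_quadrants(raster_values(mask))
  vapply(tiles, function(t) sum(t$native_image == 1), numeric(1))
}

#' Mosaic-level area report against a reference mask
#'
#' One row per model: vegetation pixel count, area in m^2, mosaic-level IoU
#' against the reference, and RMSE over per-quadrant foreground pixel counts
#' (predicted vs reference).  A reference row (IoU 1, RMSE 0) is appended.
#'
#' @param predictions Named list of `mosaic_prediction`s, [binary_mask]s or
#'   0/1 matrices aligned to the reference.
#' @param reference The reference [binary_mask] (ground truth).
#' @param pixel_area_m2 Ground area per pixel.
#' @return A data frame of class `area_report` with columns `model`,
#'   `pixel_count`, `area_m2`, `iou`, `rmse`.
#' @export
build_area_report <- function(predictions, reference,
                              pixel_area_m2 = default_pixel_area()) {
  if (!length(predictions) || is.null(names(predictions)) ||
      any(names(predictions) == ""))
    stopf("predictions must be a non-empty named list")
  ref_v <- raster_values(reference)
  ref_q <- quadrant_counts(ref_v)
  rows <- lapply(names(predictions), function(nm) {
    p <- predictions[[nm]]
    if (inherits(p, "mosaic_prediction")) p <- p$full_mask
    pv <- raster_values(p)
    if (!all(dim(pv) == dim(ref_v)))
      stopf("prediction '%s' is not aligned to the reference", nm)
    cnt <- count_foreground(pv)
    data.frame(model = nm, pixel_count = cnt,
               area_m2 = area_from_count(cnt, pixel_area_m2),
               iou = iou(pv, ref_v),
               rmse = rmse(ref_q, quadrant_counts(pv)))
  })
  ref_cnt <- count_foreground(ref_v)
  rows[[length(rows) + 1L]] <- data.frame(
    model = "reference", pixel_count = ref_cnt,
    area_m2 = area_from_count(ref_cnt, pixel_area_m2), iou = 1.0, rmse = 0.0)
  out <- do.call(rbind, rows)
  class(out) <- c("area_report", "data.frame")
  out
}

#' @export
print.area_report <- function(x, ...) {
  cat("Vegetation area report\n")
  df <- data.frame(model = x$model,
                   pixel_count = format(x$pixel_count, big.mark = ","),
                   area_m2 = sprintf("%.4f", x$area_m2),
                   iou = sprintf("%.4f", x$iou),
                   rmse = sprintf("%.4f", x$rmse))
  print(df, row.names = FALSE, right = TRUE)
  invisible(x)
}
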