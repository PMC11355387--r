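# Quadrant tiling, rescaling to model resolution, augmentation, and the
# train/validation/test dataset build.
#
# Coordinate convention: 0-based offsets, row-major top-left origin,
# half-open extents.  For odd parent dimensions the top/left quadrants take
# the extra pixel.

tile_record <- function(parent_id, quadrant_index, row_offset, col_offset,
                        native_image = NULL, native_mask = NULL,
                        model_image = NULL, model_mask = NULL,
                        aug = "identity", capture_style = NA_character_) {
  structure(list(parent_id = parent_id,
                 quadrant_index = as.integer(quadrant_index),
                 row_offset = as.integer(row_offset),
                 col_offset = as.integer(col_offset),
                 native_image = native_image, native_mask = native_mask,
                 model_image = model_image, model_mask = model_mask,
                 aug = aug, capture_style = capture_style),
            class = "tile_record")
}

#' Split an orthophoto (and optionally its mask) into four quadrants
#'
#' Quadrants are ordered top-left, top-right, bottom-left, bottom-right
#' (indices 0--3) and tile the parent exactly, with no gaps or overlap; for
#' odd dimensions the top/left quadrants take the extra pixel.  A 4000 x 2250
#' raster splits into four 2000 x 1125 tiles.
#'
#' @param image An [ortho_image] or a plain `H x W (x 3)` array.
#' @param mask Optional aligned [binary_mask] or `H x W` matrix.
#' @return A list of four `tile_record` objects carrying the native-resolution
#'   rasters and their 0-based row/column offsets.
#' @seealso [reassemble_quadrants()], [resize_pair()]
#' @export
split_into_quadrants <- function(image, mask = NULL) {
  px <- raster_values(image)
  di <- dim(px)
  H <- di[1]; W <- di[2]
  if (H < 2L || W < 2L) stopf("raster must be at least 2 x 2")
  mv <- if (is.null(mask)) NULL else raster_values(mask)
  if (!is.null(mv) && !all(dim(mv)[1:2] == c(H, W)))
    stopf("image and mask shapes differ")
  hs <- as.integer(ceiling(H / 2)); ws <- as.integer(ceiling(W / 2))
  id <- raster_id(image)
  bounds <- list(c(1L, hs, 1L, ws), c(1L, hs, ws + 1L, W),
                 c(hs + 1L, H, 1L, ws), c(hs + 1L, H, ws + 1L, W))
  lapply(seq_along(bounds), function(q) {
    b <- bounds[[q]]
    sub_img <- if (length(di) == 3L) px[b[1]:b[2], b[3]:b[4], , drop = FALSE]
               else px[b[1]:b[2], b[3]:b[4], drop = FALSE]
    sub_mask <- if (is.null(mv)) NULL else mv[b[1]:b[2], b[3]:b[4], drop = FALSE]
    tile_record(id, q - 1L, b[1] - 1L, b[3] - 1L,
                native_image = sub_img, native_mask = sub_mask)
  })
}

#' Reassemble quadrant tiles into the parent raster
#'
#' Exact inverse of [split_into_quadrants()] on the native rasters.
#' Placement is governed by the recorded offsets, not by list order.  Tiles
#' must share a parent id and cover the canvas exactly.
#'
#' @param tiles List of four `tile_record`s at native resolution.
#' @return A list with `image` (array, or `NULL` if tiles carry no image)
#'   and `mask` (matrix or `NULL`).
#' @export
reassemble_quadrants <- function(tiles) {
  if (!length(tiles)) stopf("no tiles to reassemble")
  ids <- vapply(tiles, function(t) t$parent_id, character(1))
  if (length(unique(ids)) != 1L)
    stopf("tiles have mismatched parent ids: %s",
          paste(unique(ids), collapse = ", "))
  ref <- function(t) if (!is.null(t$native_mask)) dim(t$native_mask)[1:2]
                     else dim(t$native_image)[1:2]
  hw <- vapply(tiles, ref, integer(2))
  ro <- vapply(tiles, function(t) t$row_offset, integer(1))
  co <- vapply(tiles, function(t) t$col_offset, integer(1))
  H <- max(ro + hw[1, ]); W <- max(co + hw[2, ])
  covered <- matrix(0L, H, W)
  has_img <- !is.null(tiles[[1]]$native_image)
  has_mask <- !is.null(tiles[[1]]$native_mask)
  img <- if (has_img) {
    d3 <- length(dim(tiles[[1]]$native_image)) == 3L
    if (d3) array(0L, c(H, W, dim(tiles[[1]]$native_image)[3])) else matrix(0L, H, W)
  }
  mask <- if (has_mask) matrix(0L, H, W)
  for (t in tiles) {
    ii <- (t$row_offset + 1L):(t$row_offset + ref(t)[1])
    jj <- (t$col_offset + 1L):(t$col_offset + ref(t)[2])
    covered[ii, jj] <- covered[ii, jj] + 1L
    if (has_img) {
      if (length(dim(img)) == 3L) img[ii, jj, ] <- t$native_image
      else img[ii, jj] <- t$native_image
    }
    if (has_mask) mask[ii, jj] <- t$native_mask
  }
  if (any(covered != 1L))
    stopf("tile offsets/shapes do not tile the parent exactly")
  list(image = if (has_img) img else NULL,
       mask = if (has_mask) mask else NULL)
}

#' Rescale a tile to model resolution
#'
#' The image is resampled with bilinear interpolation; the mask with
#' nearest-neighbour so it stays strictly binary.
#'
#' @param tile A `tile_record` with native rasters.
#' @param model_size Square model resolution (default 160).
#' @return The tile with `model_image` (8-bit integer array) and
#'   `model_mask` filled in.
#' @export
resize_pair <- function(tile, model_size = 160L) {
  if (!is_count(model_size, 8)) stopf("model_size must be an integer >= 8")
  if (is.null(tile$native_image) && is.null(tile$native_mask))
    stopf("tile carries no native rasters")
  if (!is.null(tile$native_image)) {
    img <- round(resize_raster(tile$native_image, model_size, model_size,
                               bilinear = TRUE))
    storage.mode(img) <- "integer"
    tile$model_image <- img
  }
  if (!is.null(tile$native_mask)) {
    mk <- resize_raster(tile$native_mask, model_size, model_size,
                        bilinear = FALSE)
    storage.mode(mk) <- "integer"
    tile$model_mask <- mk
  }
  tile
}

#' Augment a model-resolution tile
#'
#' Returns the four training variants used by the dataset build -- identity,
#' horizontal flip, 90-degree rotation and 180-degree rotation -- each
#' applied identically to image and mask.
#'
#' @param tile A `tile_record` with square model-resolution rasters.
#' @return A list of exactly four `tile_record`s.
#' @export
augment_pair <- function(tile) {
  if (is.null(tile$model_image) && is.null(tile$model_mask))
    stopf("tile has no model-resolution rasters; call resize_pair() first")
  ref <- if (!is.null(tile$model_image)) dim(tile$model_image)[1:2]
         else dim(tile$model_mask)[1:2]
  if (ref[1] != ref[2])
    stopf("model rasters must be square for 90-degree rotation")
  tfs <- list(identity = identity, hflip = hflip,
              rot90 = rot90cw, rot180 = rot180)
  lapply(names(tfs), function(nm) {
    f <- tfs[[nm]]
    out <- tile
    out$aug <- nm
    if (!is.null(tile$model_image)) out$model_image <- apply_planes(tile$model_image, f)
    if (!is.null(tile$model_mask)) out$model_mask <- f(tile$model_mask)
    out
  })
}

#' Build a tiled, augmented train/validation/test dataset
#'
#' Scenes are split at the source-image level (never at tile level, to keep
#' quadrants of one orthophoto out of different splits), each scene is cut
#' into four quadrants, quadrants are rescaled to `model_size`, and the four
#' flip/rotation variants are generated for training tiles only.
#'
#' @param scenes Either a list whose elements carry `image` and `mask`
#'   (e.g. the output of [generate_scene()]) or a function `f(i)` returning
#'   such an element, in which case `n_scenes` must be given.  A generator
#'   keeps only one native-resolution scene in memory at a time.
#' @param train_fraction,val_fraction Fractions of source images assigned to
#'   training and validation; `train_fraction` in (0,1), `val_fraction` in
#'   \[0,1), sum below 1.  The remainder is the test set.
#' @param seed Seed for the membership shuffle.
#' @param model_size Model input resolution (default 160).
#' @param n_scenes Number of scenes when `scenes` is a generator function.
#' @param keep_native Keep native-resolution rasters on the tiles (memory
#'   heavy for survey-size mosaics; default drops them after rescaling).
#' @return An object of class `dataset_split` with `train_tiles` (after
#'   augmentation), `validation_tiles`, `test_tiles`, `membership`,
#'   `split_seed` and an `accounting` list (sources, tiles and augmented
#'   counts per split).
#' @examples
#' scenes <- lapply(1:4, function(i)
#'   generate_scene(scene_params(200, 180, n_rows = 2, plants_per_row = 3,
#'                               seed = i)))
#' ds <- build_dataset(scenes, train_fraction = 0.5, val_fraction = 0.25,
#'                     seed = 1, model_size = 32)
#' ds$accounting$train_augmented  # 2 scenes x 4 quadrants x 4 variants = 32
#' @export
build_dataset <- function(scenes, train_fraction = 0.66, val_fraction = 0.10,
                          seed = 1L, model_size = 160L, n_scenes = NULL,
                          keep_native = FALSE) {
  fetch <- if (is.function(scenes)) scenes else function(i) scenes[[i]]
  n <- if (is.function(scenes)) n_scenes else length(scenes)
  if (is.null(n) || !is_count(n, 2))
    stopf("need at least two scenes (pass n_scenes for a generator)")
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (!is_number(val_fraction) || val_fraction < 0 || val_fraction >= 1)
    stopf("val_fraction must be in [0, 1)")
  if (train_fraction + val_fraction >= 1)
    stopf("train_fraction + val_fraction must be below 1")
  n_train <- as.integer(round(train_fraction * n))
  n_val <- as.integer(round(val_fraction * n))
  n_test <- n - n_train - n_val
  if (n_train < 1L || n_test < 1L)
    stopf("too few scenes to populate the training and test splits")
  perm <- with_seed(as.integer(seed), sample.int(n))
  membership <- rep("test", n)
  membership[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0L) membership[perm[n_train + seq_len(n_val)]] <- "validation"

  out <- list(train = list(), validation = list(), test = list())
  ids <- list(train = character(), validation = character(), test = character())
  n_train_tiles <- 0L
  for (i in seq_len(n)) {
    sc <- fetch(i)
    grp <- membership[i]
    style <- if (!is.null(sc$scene)) sc$scene$params$capture_style else NA_character_
    tiles <- split_into_quadrants(sc$image, sc$mask)
    tiles <- lapply(tiles, function(t) {
      t <- resize_pair(t, model_size)
      t$capture_style <- style
      if (!keep_native) t$native_image <- t$native_mask <- NULL
      t
    })
    ids[[grp]] <- c(ids[[grp]], tiles[[1]]$parent_id)
    if (grp == "train") {
      n_train_tiles <- n_train_tiles + length(tiles)
      tiles <- do.call(c, lapply(tiles, augment_pair))
    }
    out[[grp]] <- c(out[[grp]], tiles)
  }
  if (anyDuplicated(unlist(ids)))
    stopf("duplicate scene ids across splits; give scenes distinct ids/seeds")

  accounting <- list(
    n_scenes = n, train_sources = n_train, validation_sources = n_val,
    test_sources = n_test, train_tiles = n_train_tiles,
    train_augmented = length(out$train),
    validation_tiles = length(out$validation),
    test_tiles = length(out$test))
  stopifnot(accounting$train_augmented == 4L * accounting$train_tiles)
  structure(list(train_tiles = out$train,
                 validation_tiles = out$validation,
                 test_tiles = out$test,
                 membership = ids,
                 split_seed = as.integer(seed),
                 model_size = as.integer(model_size),
                 accounting = accounting),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  a <- x$accounting
  cat("Tiled segmentation dataset\n")
  cat(sprintf("  sources: %d train / %d validation / %d test (seed %d)\n",
              a$train_sources, a$validation_sources, a$test_sources,
              x$split_seed))
  cat(sprintf("  tiles:   %d train (%d before augmentation), %d validation, %d test\n",
              a$train_augmented, a$train_tiles, a$validation_tiles,
              a$test_tiles))
  cat(sprintf("  model resolution: %d x %d\n", x$model_size, x$model_size))
  invisible(x)
}
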