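test_that("quadrant split follows the odd-dimension rule and records offsets", {
  m <- matrix(1:25, 5, 5)
  tiles <- split_into_quadrants(m)
  dims <- lapply(tiles, function(t) dim(t$native_image))
  expect_equal(dims, list(c(3L, 3L), c(3L, 2L), c(2L, 3L), c(2L, 2L)))
  expect_equal(vapply(tiles, `[[`, integer(1), "quadrant_index"), 0:3)
  expect_equal(vapply(tiles, `[[`, integer(1), "row_offset"), c(0L, 0L, 3L, 3L))
  expect_equal(vapply(tiles, `[[`, integer(1), "col_offset"), c(0L, 3L, 0L, 3L))
  expect_error(split_into_quadrants(rand_image(8, 8), rand_mask(8, 6)),
               "differ")
})

test_that("foreground counts are conserved by the split", {
  set.seed(42)
  for (rep in 1:20) {
    mk <- rand_mask(64, 36)
    tiles <- split_into_quadrants(rand_image(64, 36), mk)
    per_tile <- vapply(tiles, function(t) sum(t$native_mask == 1L), numeric(1))
    expect_equal(sum(per_tile), sum(mk == 1L))
  }
})

test_that("reassembly inverts the split bit-exactly, independent of order", {
  set.seed(7)
  img <- rand_image(37, 51)
  mk <- rand_mask(37, 51)
  tiles <- split_into_quadrants(ortho_image(img, id = "p"),
                                binary_mask(mk, id = "p"))
  back <- reassemble_quadrants(tiles)
  expect_identical(back$image, img)
  expect_identical(back$mask, mk)
  shuffled <- tiles[c(3, 1, 4, 2)]
  expect_identical(reassemble_quadrants(shuffled)$mask, mk)

  bad <- tiles
  bad[[2]]$parent_id <- "other"
  expect_error(reassemble_quadrants(bad), "parent ids")
  bad2 <- tiles
  bad2[[2]]$col_offset <- 0L
  expect_error(reassemble_quadrants(bad2), "exactly")
})

test_that("rescaling keeps images 8-bit and masks binary", {
  expect_error(resize_pair(split_into_quadrants(rand_image(16, 16))[[1]],
                           model_size = 4), ">= 8")
  tiles <- split_into_quadrants(rand_image(100, 80, seed = 1),
                                matrix(1L, 100, 80))
  t1 <- resize_pair(tiles[[1]], 32)
  expect_equal(dim(t1$model_image), c(32L, 32L, 3L))
  expect_true(all(t1$model_mask == 1L))      # constant raster stays constant
  tiles2 <- split_into_quadrants(rand_image(100, 80, seed = 2),
                                 rand_mask(100, 80, seed = 3))
  t2 <- resize_pair(tiles2[[2]], 32)
  expect_true(all(t2$model_mask %in% c(0L, 1L)))
  expect_true(all(t2$model_image >= 0L & t2$model_image <= 255L))
})

test_that("augmentation yields the four paired variants", {
  tile <- resize_pair(split_into_quadrants(rand_image(64, 64, seed = 5),
                                           rand_mask(64, 64, seed = 6))[[1]],
                      16)
  aug <- augment_pair(tile)
  expect_length(aug, 4L)
  expect_setequal(vapply(aug, `[[`, character(1), "aug"),
                  c("identity", "hflip", "rot90", "rot180"))
  # identical geometry for image and mask; counts preserved
  counts <- vapply(aug, function(t) sum(t$model_mask), numeric(1))
  expect_true(all(counts == counts[1]))
  # 180-degree rotation is an involution
  r180 <- aug[[which(vapply(aug, `[[`, character(1), "aug") == "rot180")]]
  again <- augment_pair(r180)
  r180r180 <- again[[which(vapply(again, `[[`, character(1), "aug") == "rot180")]]
  expect_identical(r180r180$model_mask, tile$model_mask)
  expect_identical(r180r180$model_image, tile$model_image)

  # non-square model rasters cannot be rotated shape-preservingly
  bad <- tile
  bad$model_image <- bad$model_image[1:8, , , drop = FALSE]
  bad$model_mask <- bad$model_mask[1:8, , drop = FALSE]
  expect_error(augment_pair(bad), "square")
})

test_that("dataset build splits sources, augments training tiles, and accounts", {
  scenes <- lapply(1:4, function(i)
    generate_scene(small_params(seed = 100 + i)))
  ds <- build_dataset(scenes, train_fraction = 0.5, val_fraction = 0.25,
                      seed = 3, model_size = 32)
  a <- ds$accounting
  expect_equal(a$train_sources, 2L)
  expect_equal(a$validation_sources, 1L)
  expect_equal(a$test_sources, 1L)
  expect_equal(a$train_tiles, 8L)          # 2 images x 4 quadrants
  expect_equal(a$train_augmented, 32L)     # x 4 augmentations
  expect_length(ds$train_tiles, 32L)

  # seeded determinism of membership
  ds2 <- build_dataset(scenes, train_fraction = 0.5, val_fraction = 0.25,
                       seed = 3, model_size = 32)
  expect_identical(ds$membership, ds2$membership)

  # leakage freedom: no source image in two splits
  all_ids <- unlist(ds$membership)
  expect_equal(anyDuplicated(all_ids), 0L)
  tile_groups <- list(train = ds$train_tiles, validation = ds$validation_tiles,
                      test = ds$test_tiles)
  for (grp in names(tile_groups)) {
    ids <- unique(vapply(tile_groups[[grp]], `[[`, character(1), "parent_id"))
    expect_true(all(ids %in% ds$membership[[grp]]))
  }

  expect_error(build_dataset(scenes, train_fraction = 0.9,
                             val_fraction = 0.09), "too few")
})

test_that("the survey-campaign split ratio reproduces 294 training / 149 test sources", {
  gen <- function(i) mock_scene(24, 16, sprintf("m%03d", i))
  ds <- build_dataset(gen, n_scenes = 443L, train_fraction = 294 / 443,
                      val_fraction = 0, seed = 1, model_size = 8)
  expect_equal(ds$accounting$train_sources, 294L)
  expect_equal(ds$accounting$test_sources, 149L)
  expect_equal(ds$accounting$validation_sources, 0L)
  expect_equal(ds$accounting$train_augmented, 4704L)
})

test_that("every mask emitted by the dataset build is binary", {
  scenes <- lapply(1:3, function(i) generate_scene(small_params(seed = 30 + i)))
  ds <- build_dataset(scenes, train_fraction = 0.4, val_fraction = 0.3,
                      seed = 5, model_size = 16)
  for (t in c(ds$train_tiles, ds$validation_tiles, ds$test_tiles))
    expect_true(all(t$model_mask %in% c(0L, 1L)))
})
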