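test_that("scene parameters are validated", {
  expect_error(scene_params(width_px = 100), ">= 160")
  expect_error(scene_params(plants_per_row = 0), "plants_per_row")
  expect_error(scene_params(pixel_area_m2 = 0), "positive")
  expect_error(scene_params(paddle_count_range = c(3, 1)), "interval")
  expect_error(scene_params(paddle_axis_px = c(-1, 5)), "interval")
  expect_error(scene_params(shadow_strength = 2), "shadow_strength")
  expect_error(scene_params(capture_style = "orbital"), "capture_style|arg")
})

test_that("pixel scale matches the survey reference (54.1950 m2 over 128,959 px)", {
  expect_equal(default_pixel_area(), 54.1950 / 128959)
  expect_equal(default_pixel_area(), 4.202498e-4, tolerance = 1e-6)
  expect_equal(sqrt(default_pixel_area()), 0.0205, tolerance = 1e-2)
  expect_equal(128959 * default_pixel_area(), 54.1950)
})

test_that("generated scenes are seeded and internally consistent", {
  a <- generate_scene(small_params(seed = 11))
  b <- generate_scene(small_params(seed = 11))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$values, b$mask$values)
  c <- generate_scene(small_params(seed = 12))
  expect_false(identical(a$image$pixels, c$image$pixels))

  # ground truth is exact by construction
  expect_identical(sort(unique(as.vector(a$mask$values))), c(0L, 1L))
  expect_equal(a$scene$true_foreground_px, sum(a$mask$values == 1))
  expect_equal(a$scene$true_area_m2,
               a$scene$true_foreground_px * a$image$pixel_area_m2)
  expect_equal(a$scene$true_area_m2 / a$image$pixel_area_m2,
               round(a$scene$true_area_m2 / a$image$pixel_area_m2))
})

test_that("a paddle-free configuration renders an empty mask", {
  sc <- generate_scene(small_params(seed = 2, paddle_count_range = c(0, 0)))
  expect_true(all(sc$mask$values == 0L))
  expect_equal(sc$scene$true_area_m2, 0)
})

test_that("canopy cover of a 400x225 scene is plausible and equals the rendered count", {
  sc <- generate_scene(scene_params(width_px = 400, height_px = 225,
                                    n_rows = 3, plants_per_row = 4, seed = 7))
  # exhaustive pixel scan, independent of the generator's own counter
  fg <- 0L
  v <- sc$mask$values
  for (j in seq_len(ncol(v))) fg <- fg + sum(v[, j] == 1L)
  frac <- fg / (400 * 225)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.60)
  expect_equal(sc$scene$true_foreground_px, fg)
})

test_that("more plants per row does not reduce expected cover (20 seeds)", {
  frac <- function(ppr, seed)
    mean(generate_scene(small_params(seed = seed, plants_per_row = ppr,
                                     paddle_axis_px = c(5, 12)))$mask$values)
  f2 <- vapply(1:20, function(s) frac(2L, s), numeric(1))
  f5 <- vapply(1:20, function(s) frac(5L, s), numeric(1))
  expect_gte(mean(f5), mean(f2))
})

test_that("capture variants preserve alignment, binarity and scale", {
  sc <- generate_scene(small_params(seed = 3))
  expect_error(capture_variant(sc$image, sc$mask, "sideways"), "unknown")

  # identity configuration returns the inputs untouched
  idn <- capture_variant(sc$image, sc$mask, "nadir_90", illum = 0)
  expect_identical(idn$image$pixels, sc$image$pixels)

  for (style in c("nadir_90", "oblique_45", "oblique_135")) {
    cv <- capture_variant(sc$image, sc$mask, style, seed = 9)
    expect_identical(dim(cv$image$pixels), dim(sc$image$pixels))
    expect_true(all(cv$mask$values %in% c(0L, 1L)))
  }

  # oblique shear moves little mass off-frame: counts within 10% of nadir
  nadir_fg <- sum(sc$mask$values)
  obl <- capture_variant(sc$image, sc$mask, "oblique_45", seed = 9)
  expect_lt(abs(sum(obl$mask$values) - nadir_fg), 0.10 * nadir_fg)
})

test_that("oblique capture styles shear the scene deterministically", {
  p45 <- small_params(seed = 4, capture_style = "oblique_45")
  a <- generate_scene(p45)
  b <- generate_scene(p45)
  expect_identical(a$mask$values, b$mask$values)
  nadir <- generate_scene(small_params(seed = 4))
  expect_false(identical(a$mask$values, nadir$mask$values))
  expect_equal(a$scene$true_foreground_px, sum(a$mask$values))
})

test_that("scenes round-trip through PNG + JSON sidecar", {
  sc <- generate_scene(small_params(seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths["image"])
  expect_equal(dim(img), dim(sc$image$pixels))
  expect_equal(round(img * 255), sc$image$pixels, ignore_attr = TRUE)
  mk <- png::readPNG(paths["mask"])
  expect_identical(sort(unique(round(as.vector(mk) * 255))),
                   c(0, 255)[c(TRUE, any(sc$mask$values == 1))])
  expect_equal(round(mk * 255) / 255, sc$mask$values, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paths["sidecar"])
  expect_equal(meta$true_foreground_px, sc$scene$true_foreground_px)
  expect_equal(meta$seed, 5)
})
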