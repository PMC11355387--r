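# Synthetic cactus-field orthophotos with exact ground truth.
#
# The generator emulates nadir/oblique UAV orthophotos of a row-planted
# Opuntia (prickly pear) field: paddle-shaped green canopies (clusters of
# overlapping rotated ellipses, one cluster per plant) arranged in horizontal
# furrow bands on textured brown soil, with per-paddle shadows and a mild
# illumination gradient.  Every scene carries its exact foreground pixel
# count and ground area, replacing manual mask annotation as the reference.

#' Ground area covered by one orthomosaic pixel
#'
#' The default scale of the synthetic scenes: the reference survey mosaic
#' covers 54.1950 m^2 of canopy in 128,959 vegetation pixels, so one pixel
#' maps to 54.1950 / 128959 m^2 (a ground sampling distance of about 2.05 cm).
#'
#' @return Ground area per pixel in square metres (about 4.2025e-4).
#' @examples
#' default_pixel_area() * 128959  # 54.195 m^2
#' sqrt(default_pixel_area())     # implied GSD in metres
#' @export
default_pixel_area <- function() 54.1950 / 128959

#' Parameters of a synthetic cactus-field scene
#'
#' @param width_px,height_px Scene dimensions in pixels (at least 160 each).
#'   Defaults match the study imagery (4000 x 2250).
#' @param pixel_area_m2 Ground area per pixel in m^2; see
#'   [default_pixel_area()].
#' @param n_rows Number of planting furrows (horizontal bands).
#' @param plants_per_row Plants per furrow.
#' @param paddle_count_range Integer interval: paddles (cladode ellipses) per
#'   plant.  `c(0, 0)` draws no canopy at all.
#' @param paddle_axis_px Real interval for ellipse semi-axes in pixels.
#'   `NULL` scales the interval to the furrow/plant spacing so canopies stay
#'   clear of their neighbours at any scene size.
#' @param canopy_hue_jitter,soil_texture_scale,shadow_strength,illumination_gradient
#'   Appearance controls in `[0, 1]`.
#' @param capture_style One of `"nadir_90"`, `"oblique_45"`, `"oblique_135"`.
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @return An object of class `scene_params`.
#' @seealso [generate_scene()]
#' @export
scene_params <- function(width_px = 4000L, height_px = 2250L,
                         pixel_area_m2 = default_pixel_area(),
                         n_rows = 6L, plants_per_row = 12L,
                         paddle_count_range = c(1L, 8L),
                         paddle_axis_px = NULL,
                         canopy_hue_jitter = 0.3,
                         soil_texture_scale = 0.5,
                         shadow_strength = 0.4,
                         illumination_gradient = 0.15,
                         capture_style = "nadir_90",
                         seed = 1L) {
  if (!is_count(width_px, 160) || !is_count(height_px, 160))
    stopf("width_px and height_px must be integers >= 160")
  if (!is_number(pixel_area_m2) || pixel_area_m2 <= 0)
    stopf("pixel_area_m2 must be a positive number")
  if (!is_count(n_rows) || !is_count(plants_per_row, 0L))
    stopf("n_rows must be >= 1 and plants_per_row >= 1")
  if (plants_per_row < 1L) stopf("plants_per_row must be >= 1")
  if (length(paddle_count_range) != 2L || any(paddle_count_range < 0) ||
      paddle_count_range[1] > paddle_count_range[2])
    stopf("paddle_count_range must be a non-empty non-negative interval")
  if (is.null(paddle_axis_px)) {
    ref <- min(height_px / n_rows, width_px / plants_per_row)
    paddle_axis_px <- c(0.08, 0.22) * ref
  }
  if (length(paddle_axis_px) != 2L || any(paddle_axis_px < 0) ||
      paddle_axis_px[1] > paddle_axis_px[2])
    stopf("paddle_axis_px must be a non-empty non-negative interval")
  for (nm in c("canopy_hue_jitter", "soil_texture_scale", "shadow_strength",
               "illumination_gradient")) {
    v <- get(nm)
    if (!is_number(v) || v < 0 || v > 1) stopf("%s must be in [0, 1]", nm)
  }
  capture_style <- match.arg(capture_style,
                             c("nadir_90", "oblique_45", "oblique_135"))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_area_m2 = pixel_area_m2,
                 n_rows = as.integer(n_rows),
                 plants_per_row = as.integer(plants_per_row),
                 paddle_count_range = as.integer(round(paddle_count_range)),
                 paddle_axis_px = as.numeric(paddle_axis_px),
                 canopy_hue_jitter = canopy_hue_jitter,
                 soil_texture_scale = soil_texture_scale,
                 shadow_strength = shadow_strength,
                 illumination_gradient = illumination_gradient,
                 capture_style = capture_style,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' RGB orthophoto raster with a ground scale
#'
#' @param pixels `H x W x 3` array of 8-bit intensities (0--255).
#' @param pixel_area_m2 Ground area per pixel in m^2.
#' @param id Identifier string.
#' @return An object of class `ortho_image`.
#' @export
ortho_image <- function(pixels, pixel_area_m2 = default_pixel_area(),
                        id = "ortho") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stopf("pixels must be a H x W x 3 array")
  if (!is_number(pixel_area_m2) || pixel_area_m2 <= 0)
    stopf("pixel_area_m2 must be positive")
  structure(list(pixels = pixels, pixel_area_m2 = pixel_area_m2,
                 id = as.character(id)),
            class = "ortho_image")
}

#' Binary raster mask aligned to an image
#'
#' @param values `H x W` matrix over \{0, 1\} (1 = vegetation).
#' @param id Identifier of the paired image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, id = "mask") {
  if (!is.matrix(values)) stopf("values must be a matrix")
  check_binary_values(values)
  structure(list(values = values, id = as.character(id)),
            class = "binary_mask")
}

# Pixels of one filled rotated ellipse, clipped to the frame: bounding-box
# row/column indices plus an inside indicator, or NULL when fully outside.
ellipse_region <- function(cy, cx, a, b, theta, H, W) {
  r <- ceiling(max(a, b))
  i0 <- max(1L, as.integer(floor(cy - r))); i1 <- min(H, as.integer(ceiling(cy + r)))
  j0 <- max(1L, as.integer(floor(cx - r))); j1 <- min(W, as.integer(ceiling(cx + r)))
  if (i0 > i1 || j0 > j1) return(NULL)
  ii <- i0:i1; jj <- j0:j1
  dy <- ii - cy; dx <- jj - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) ct * x + st * y)
  v <- outer(dy, dx, function(y, x) -st * x + ct * y)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(NULL)
  list(ii = ii, jj = jj, inside = inside)
}

#' Generate a synthetic cactus-field orthophoto with ground truth
#'
#' Renders a row-planted field scene: textured brown soil, paddle-shaped
#' canopies in furrow bands, soft shadows and an illumination gradient.  The
#' returned ground truth is exact by construction: the mask is the rendered
#' union of canopy ellipses and the true area is the foreground count times
#' the pixel ground area.
#'
#' @param params A [scene_params()] object.
#' @return A list with components `image` ([ortho_image]), `mask`
#'   ([binary_mask]) and `scene` (class `field_scene`: the parameters, the
#'   per-paddle records, `true_foreground_px` and `true_area_m2`).
#' @examples
#' sc <- generate_scene(scene_params(400, 225, n_rows = 3,
#'                                   plants_per_row = 4, seed = 7))
#' sc$scene$true_foreground_px == sum(sc$mask$values)
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "scene_params"))
    stopf("params must be created by scene_params()")
  H <- params$height_px; W <- params$width_px
  with_seed(params$seed, {
    # soil: low-frequency value noise plus high-frequency speckle, brown hues
    amp <- params$soil_texture_scale
    if (amp > 0) {
      gh <- 24L; gw <- max(2L, as.integer(round(24 * W / H)))
      coarse <- matrix(runif(gh * gw, -1, 1), gh, gw)
      lowf <- resize_raster(coarse, H, W, bilinear = TRUE)
      speck <- matrix(runif(H * W, -1, 1), H, W)
      noise <- 0.75 * lowf + 0.25 * speck
    } else {
      noise <- matrix(0, H, W)
    }
    soil <- c(128, 101, 72)
    shade <- 1 + 0.30 * amp * noise
    chR <- soil[1] * shade; chG <- soil[2] * shade; chB <- soil[3] * shade
    rm(shade)
    maskm <- matrix(0L, H, W)

    # plant layout: one horizontal furrow band per row
    rec <- list()
    if (params$paddle_count_range[2] > 0L && params$plants_per_row > 0L) {
      row_h <- H / params$n_rows
      sp <- W / params$plants_per_row
      ax <- params$paddle_axis_px
      green <- c(62, 112, 48)
      for (r in seq_len(params$n_rows)) {
        base_y <- (r - 0.5) * row_h
        for (p in seq_len(params$plants_per_row)) {
          cx <- (p - 0.5) * sp + rnorm(1, 0, 0.10 * sp)
          cy <- base_y + rnorm(1, 0, 0.08 * row_h)
          k <- if (params$paddle_count_range[1] == params$paddle_count_range[2])
            params$paddle_count_range[1]
          else sample(params$paddle_count_range[1]:params$paddle_count_range[2], 1L)
          if (k < 1L) next
          for (q in seq_len(k)) {
            a <- runif(1, ax[1], ax[2]); b <- runif(1, ax[1], ax[2])
            if (b > a) { tmp <- a; a <- b; b <- tmp }
            rad <- runif(1, 0, 0.9 * ax[2])
            phi <- runif(1, 0, 2 * pi)
            th <- runif(1, 0, pi)
            jit <- params$canopy_hue_jitter *
              c(runif(1, -22, 22), runif(1, -26, 26), runif(1, -16, 16))
            rec[[length(rec) + 1L]] <- data.frame(
              row = r, plant = p,
              cy = cy + rad * sin(phi), cx = cx + rad * cos(phi),
              a = a, b = b, theta = th,
              col_r = green[1] + jit[1], col_g = green[2] + jit[2],
              col_b = green[3] + jit[3])
          }
        }
      }
    }
    paddles <- if (length(rec)) do.call(rbind, rec) else
      data.frame(row = integer(), plant = integer(), cy = numeric(),
                 cx = numeric(), a = numeric(), b = numeric(),
                 theta = numeric(), col_r = numeric(), col_g = numeric(),
                 col_b = numeric())

    # shadows first (offset toward lower right), then canopy paint
    if (params$shadow_strength > 0 && nrow(paddles)) {
      dk <- 1 - 0.55 * params$shadow_strength
      for (q in seq_len(nrow(paddles))) {
        pd <- paddles[q, ]
        reg <- ellipse_region(pd$cy + 0.35 * pd$a, pd$cx + 0.35 * pd$a,
                              pd$a, pd$b, pd$theta, H, W)
        if (is.null(reg)) next
        sub <- chR[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- sub[reg$inside] * dk
        chR[reg$ii, reg$jj] <- sub
        sub <- chG[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- sub[reg$inside] * dk
        chG[reg$ii, reg$jj] <- sub
        sub <- chB[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- sub[reg$inside] * dk
        chB[reg$ii, reg$jj] <- sub
      }
    }
    if (nrow(paddles)) {
      for (q in seq_len(nrow(paddles))) {
        pd <- paddles[q, ]
        reg <- ellipse_region(pd$cy, pd$cx, pd$a, pd$b, pd$theta, H, W)
        if (is.null(reg)) next
        tex <- 1 + noise[reg$ii, reg$jj, drop = FALSE][reg$inside] * 0.10
        sub <- chR[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- pd$col_r * tex
        chR[reg$ii, reg$jj] <- sub
        sub <- chG[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- pd$col_g * tex
        chG[reg$ii, reg$jj] <- sub
        sub <- chB[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- pd$col_b * tex
        chB[reg$ii, reg$jj] <- sub
        sub <- maskm[reg$ii, reg$jj, drop = FALSE]
        sub[reg$inside] <- 1L
        maskm[reg$ii, reg$jj] <- sub
      }
    }

    # illumination gradient across the frame width
    if (params$illumination_gradient > 0) {
      dirn <- sample(c(-1, 1), 1L)
      ramp <- 1 + params$illumination_gradient * 0.35 *
        dirn * seq(-1, 1, length.out = W)
      ramp <- rep(ramp, each = H)
      chR <- chR * ramp; chG <- chG * ramp; chB <- chB * ramp
    }

    img <- array(0L, dim = c(H, W, 3L))
    img[, , 1] <- as.integer(round(clamp(chR, 0, 255)))
    img[, , 2] <- as.integer(round(clamp(chG, 0, 255)))
    img[, , 3] <- as.integer(round(clamp(chB, 0, 255)))

    id <- sprintf("scene_%d", params$seed)
    fg <- sum(maskm)
    out <- list(
      image = ortho_image(img, params$pixel_area_m2, id = id),
      mask = binary_mask(maskm, id = id),
      scene = structure(list(params = params,
                             plant_records = paddles,
                             true_foreground_px = fg,
                             true_area_m2 = fg * params$pixel_area_m2),
                        class = "field_scene"))
    if (params$capture_style != "nadir_90") {
      cv <- capture_variant(out$image, out$mask, params$capture_style,
                            seed = params$seed + 1L)
      out$image <- cv$image
      out$mask <- cv$mask
      fg <- sum(out$mask$values)
      out$scene$true_foreground_px <- fg
      out$scene$true_area_m2 <- fg * params$pixel_area_m2
    }
    out
  })
}

#' Re-render a scene under a different capture style
#'
#' Emulates the three UAV capture configurations (nadir 90 degrees, oblique
#' 45/135 degrees) on an already-rendered orthophoto: a mild seeded
#' illumination gradient, plus -- for the oblique styles -- a fixed-direction
#' horizontal shear about the frame centre applied identically to image and
#' mask.  The mask stays binary and the raster shape is unchanged.
#'
#' @param image An [ortho_image].
#' @param mask The aligned [binary_mask].
#' @param style `"nadir_90"`, `"oblique_45"` or `"oblique_135"`.
#' @param seed Integer seed for the illumination jitter.
#' @param illum Illumination jitter amplitude; 0 disables it.
#' @param shear Shear magnitude (column shift per row, as a fraction).
#' @return A list with the transformed `image` and `mask`.
#' @export
capture_variant <- function(image, mask, style, seed = 1L,
                            illum = 0.10, shear = 0.12) {
  if (!style %in% c("nadir_90", "oblique_45", "oblique_135"))
    stopf("unknown capture style '%s'", style)
  px <- raster_values(image)
  mv <- raster_values(mask)
  H <- dim(px)[1]; W <- dim(px)[2]
  if (!all(dim(mv) == c(H, W))) stopf("image and mask are not aligned")
  if (style == "nadir_90" && illum == 0)
    return(list(image = image, mask = mask))
  with_seed(seed, {
    if (style != "nadir_90") {
      s <- if (style == "oblique_45") shear else -shear
      d <- as.integer(round(s * ((1:H) - (H + 1) / 2)))
      newpx <- px
      newmv <- mv
      for (dd in unique(d)) {
        rows <- which(d == dd)
        jsrc <- (1:W) - dd
        jimg <- clamp(jsrc, 1L, W)           # edge-replicate for the photo
        ok <- jsrc >= 1L & jsrc <= W         # zero-fill for the mask
        newpx[rows, , ] <- px[rows, jimg, , drop = FALSE]
        newmv[rows, ] <- 0L
        newmv[rows, ok] <- mv[rows, jsrc[ok], drop = FALSE]
      }
      px <- newpx; mv <- newmv
    }
    if (illum > 0) {
      dirn <- sample(c(-1, 1), 1L)
      g <- runif(1, 0.5, 1) * illum
      ramp <- rep(1 + g * dirn * seq(-1, 1, length.out = W), each = H)
      for (k in 1:3)
        px[, , k] <- as.integer(round(clamp(px[, , k] * ramp, 0, 255)))
    }
    list(image = ortho_image(px, image$pixel_area_m2,
                             id = paste0(raster_id(image), "_", style)),
         mask = binary_mask(mv, id = paste0(raster_id(mask), "_", style)))
  })
}

#' Write a scene to disk
#'
#' Writes the orthophoto as a 3-channel PNG, the mask as a single-band PNG
#' with values \{0, 255\} (255 = vegetation), and a JSON sidecar carrying the
#' seed, parameters, true foreground count and area.
#'
#' @param scene A list as returned by [generate_scene()].
#' @param dir Output directory (created if missing).
#' @param stem File stem; defaults to the scene id.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = NULL) {
  if (is.null(stem)) stem <- raster_id(scene$image)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  mask_path <- file.path(dir, paste0(stem, "_mask.png"))
  json_path <- file.path(dir, paste0(stem, ".json"))
  png::writePNG(scene$image$pixels / 255, img_path)
  png::writePNG(scene$mask$values + 0, mask_path)   # {0,1} -> {0,255} grey PNG
  meta <- list(id = raster_id(scene$image),
               seed = scene$scene$params$seed,
               params = unclass(scene$scene$params),
               true_foreground_px = scene$scene$true_foreground_px,
               true_area_m2 = scene$scene$true_area_m2,
               pixel_area_m2 = scene$image$pixel_area_m2)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = mask_path, sidecar = json_path))
}
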