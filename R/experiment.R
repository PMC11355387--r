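# End-to-end experiment: simulate a field survey, build the dataset, train
# all requested architectures, segment a held-out survey mosaic, and report
# areas/IoU/RMSE against the synthetic ground truth.

#' Default experiment configuration
#'
#' Desk-scale study conditions: 40 scenes at 800 x 448 native resolution,
#' 160 x 160 model tiles, three architectures with 16 base filters and
#' encoder depth 2, 3 epochs.  Any element can be overridden via `...` or a
#' YAML file passed to [run_experiment()].
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return A nested configuration list.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    threshold = 0.5,
    scene = list(width_px = 800L, height_px = 448L, n_scenes = 40L,
                 n_rows = 4L, plants_per_row = 8L),
    split = list(train_fraction = 0.66, val_fraction = 0.10),
    model = list(architectures = c("unet", "deeplabv3plus", "unet_xception"),
                 input_size = 160L, base_filters = 16L, depth = 2L,
                 atrous_rates = c(1L, 6L, 12L, 18L)),
    train = list(epochs = 3L, batch_size = 8L, learning_rate = 1e-3))
  ov <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_rec(cfg, ov)
}

# Scene generator shared by run_experiment and the CLI: scene i gets seed
# base_seed + i so ids are distinct and every scene reproducible.
scene_generator <- function(cfg) {
  sc <- cfg$scene
  extra <- sc[setdiff(names(sc), "n_scenes")]
  function(i) {
    args <- c(extra, list(seed = cfg$seed * 1000L + i))
    generate_scene(do.call(scene_params, args))
  }
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stopf("[%s] %s", label, conditionMessage(e)))
}

#' Run the full segmentation experiment
#'
#' Orchestrates the pipeline end to end: simulate seeded synthetic scenes,
#' build the tiled/augmented dataset, train every requested architecture
#' (best-validation-IoU checkpointing), evaluate tile-level IoU on held-out
#' tiles, segment a held-out survey mosaic per model, and assemble a
#' mosaic-level area report against the synthetic ground truth.  With an
#' `out_dir`, writes the report (CSV + JSON), per-model masks and blue
#' overlays (PNG), training histories (JSON) and a log recording seeds, a
#' configuration hash and per-stage timings.
#'
#' @param config A configuration list from [experiment_config()], a YAML
#'   file path, or `NULL` for the defaults.
#' @param quiet Suppress progress messages.
#' @return A list: `report` (an `area_report`), `tile_metrics` (per-model
#'   held-out tile IoU), `fits` (named list of `seg_fit`s), `truth`
#'   (the evaluation scene), `config`.
#' @export
run_experiment <- function(config = NULL, quiet = TRUE) {
  cfg <- if (is.null(config)) experiment_config()
         else if (is.character(config))
           do.call(experiment_config, yaml::read_yaml(config))
         else if (is.list(config)) do.call(experiment_config, config)
         else stopf("config must be NULL, a list, or a YAML path")
  t0 <- Sys.time()
  timings <- list()
  clock <- function(label, expr) {
    tt <- system.time(val <- stage(label, expr))
    timings[[label]] <<- unname(tt["elapsed"])
    val
  }

  gen <- scene_generator(cfg)
  ds <- clock("dataset",
    build_dataset(gen, n_scenes = cfg$scene$n_scenes,
                  train_fraction = cfg$split$train_fraction,
                  val_fraction = cfg$split$val_fraction,
                  seed = cfg$seed, model_size = cfg$model$input_size))

  fits <- list()
  for (arch in cfg$model$architectures) {
    spec <- seg_model_spec(arch, input_size = cfg$model$input_size,
                           base_filters = cfg$model$base_filters,
                           depth = cfg$model$depth,
                           atrous_rates = cfg$model$atrous_rates,
                           seed = cfg$seed)
    ctrl <- train_control(epochs = cfg$train$epochs,
                          batch_size = cfg$train$batch_size,
                          learning_rate = cfg$train$learning_rate,
                          seed = cfg$seed, threshold = cfg$threshold)
    if (!quiet) message("training ", arch, " ...")
    fits[[arch]] <- clock(paste0("train_", arch),
                          fit_segmenter(ds, spec = spec, control = ctrl,
                                        quiet = quiet))
  }

  tile_metrics <- clock("tile_eval", {
    rows <- lapply(names(fits), function(arch) {
      ev <- evaluate_tiles(fits[[arch]], ds$test_tiles, cfg$threshold)
      data.frame(model = arch, tile_iou = ev$mean_iou,
                 tile_rmse_px = rmse(ev$per_tile$true_px,
                                     ev$per_tile$pred_px))
    })
    do.call(rbind, rows)
  })

  # survey mosaic for Table-style quantification: first held-out test scene
  eval_idx <- which(vapply(seq_len(cfg$scene$n_scenes), function(i)
    sprintf("scene_%d", cfg$seed * 1000L + i), character(1)) %in%
    ds$membership$test)[1]
  truth <- clock("survey_scene", gen(eval_idx))
  preds <- clock("segment", {
    out <- lapply(fits, function(f)
      segment_orthomosaic(f$model, truth$image, threshold = cfg$threshold))
    names(out) <- names(fits)
    out
  })
  report <- clock("report",
    build_area_report(preds, truth$mask, truth$image$pixel_area_m2))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(report), file.path(cfg$out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(as.data.frame(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    png::writePNG(truth$mask$values + 0,
                  file.path(cfg$out_dir, "truth_mask.png"))
    for (arch in names(preds)) {
      png::writePNG(preds[[arch]]$full_mask$values + 0,
                    file.path(cfg$out_dir, sprintf("mask_%s.png", arch)))
      png::writePNG(overlay_mask(truth$image, preds[[arch]]$full_mask) / 255,
                    file.path(cfg$out_dir, sprintf("overlay_%s.png", arch)))
      jsonlite::write_json(
        c(list(best_epoch = fits[[arch]]$history$best_epoch,
               best_val_iou = fits[[arch]]$history$best_val_iou),
          as.list(fits[[arch]]$history$metrics)),
        file.path(cfg$out_dir, sprintf("history_%s.json", arch)),
        auto_unbox = TRUE, digits = NA)
    }
    cfg_hash <- tools::md5sum(
      local({
        f <- tempfile(fileext = ".yaml")
        yaml::write_yaml(cfg, f)
        f
      }))
    log_lines <- c(
      sprintf("run started: %s", format(t0)),
      sprintf("seed: %d", cfg$seed),
      sprintf("config md5: %s", unname(cfg_hash)),
      sprintf("scenes: %d at %dx%d", cfg$scene$n_scenes,
              cfg$scene$width_px, cfg$scene$height_px),
      sprintf("stage %s: %.2f s", names(timings), unlist(timings)))
    writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  }

  list(report = report, tile_metrics = tile_metrics, fits = fits,
       truth = truth, config = cfg, timings = timings)
}

#' Oracle segmentation of a mosaic from its ground truth
#'
#' Runs the complete tiled-inference pipeline with a perfect "model" that
#' returns the downscaled ground-truth mask for every tile.  The difference
#' between the resulting area estimate and the true area isolates the
#' quantisation error introduced by quadrant tiling, the rescale to model
#' resolution and the nearest-neighbour upscale.
#'
#' @param image The [ortho_image] (provides dimensions and scale).
#' @param truth The ground-truth [binary_mask].
#' @param input_size Model tile resolution.
#' @param ... Passed to [segment_orthomosaic()].
#' @return A `mosaic_prediction`.
#' @export
segment_with_oracle <- function(image, truth, input_size = 160L, ...) {
  mv <- raster_values(truth)
  oracle <- function(tile) {
    ii <- tile$abs_row_offset + seq_len(dim(tile$native_image)[1])
    jj <- tile$abs_col_offset + seq_len(dim(tile$native_image)[2])
    sub <- mv[ii, jj, drop = FALSE]
    resize_raster(sub, input_size, input_size, bilinear = FALSE)
  }
  segment_orthomosaic(oracle, image, input_size = input_size, ...)
}
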