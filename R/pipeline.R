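# Pipeline commands tying the stages together: generate -> train -> predict
# -> evaluate, driven by one YAML-able config. These functions back the
# `brightcount` command-line script (see `exec/brightcount`).

#' Default pipeline configuration
#'
#' A nested list (YAML-serialisable) describing one run: paths, the synthetic
#' scene block, dataset sizes, the enhancement pairing per branch, the
#' training budget, the model variant, and the master seed. `mode` selects
#' among the three studied variants: `"dual_enhanced"` (total counter on
#' contrast-stretched tiles + dead counter on Sobel tiles — the headline
#' method), `"dual_plain"` (same two counters, no enhancement), and
#' `"single_direct"` (one network regressing the image's viability
#' percentage directly from unenhanced tiles).
#'
#' The defaults reproduce the package's reference study conditions: 20
#' training and 5 validation frames at the published 2048x1536 geometry
#' (1080/270 tiles), truth viability spanning 13-97%, cells per frame at the
#' generator's default density. A full cycle at these sizes takes a few
#' minutes on one CPU core; shrink `scene`/`dataset` for smoke runs.
#'
#' @param ... Named overrides merged (deeply) into the defaults.
#' @return A config list of class `run_config`.
#' @export
run_config <- function(...) {
  base <- list(
    seed = 1L,
    mode = "dual_enhanced",
    run_id = NULL,
    paths = list(data_dir = "brightcount_data", out_dir = "brightcount_runs"),
    scene = list(width = 2048L, height = 1536L),
    dataset = list(
      n_train = 20L, n_val = 5L,
      viability_range = c(13, 97), density_range = NULL
    ),
    enhancement = list(
      total = "contrast", dead = "sobel",
      p_low = 1, p_high = 99
    ),
    train = list(
      epochs = 10L, batch_size = 4L, lr = 5e-3, augment = TRUE,
      channels = c(8L, 16L, 32L, 32L), stem_pool = 2L
    ),
    tile_size = 224L
  )
  cfg <- merge_config(base, list(...))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  if (!cfg$mode %in% c("dual_enhanced", "dual_plain", "single_direct")) {
    abort("`mode` must be dual_enhanced, dual_plain or single_direct.")
  }
  if (cfg$dataset$n_train < 1 || cfg$dataset$n_val < 0) {
    abort("`dataset$n_train` must be >= 1 and `dataset$n_val` >= 0.")
  }
  invisible(cfg)
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return `read_run_config()`: a `run_config`; `write_run_config()`: `path`
#'   invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config '%s' does not exist.", path))
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_dir <- function(cfg) {
  id <- cfg$run_id %||% format(Sys.time(), "%Y%m%d-%H%M%S")
  file.path(cfg$paths$out_dir, id)
}

log_line <- function(dir, ...) {
  msg <- sprintf(...)
  inform(msg)
  cat(format(Sys.time(), "%H:%M:%S "), msg, "\n",
    file = file.path(dir, "log.txt"), append = TRUE, sep = ""
  )
}

scene_from_config <- function(cfg, seed) {
  args <- cfg$scene
  args$seed <- seed
  do.call(scene_config, args)
}

branch_spec <- function(cfg, branch) {
  kind <- switch(cfg$mode,
    dual_enhanced = cfg$enhancement[[branch]],
    dual_plain = "identity",
    single_direct = "identity"
  )
  enhancement_spec(kind, p_low = cfg$enhancement$p_low, p_high = cfg$enhancement$p_high)
}

#' Generate the synthetic train/validation fixture
#'
#' Renders `n_train` + `n_val` annotated scenes (seeds derived from the
#' master seed) and writes PNGs, VIA JSONs and manifests under
#' `paths$data_dir/train` and `paths$data_dir/val`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the two manifest paths.
#' @export
cmd_generate <- function(config) {
  cfg <- config
  dir.create(cfg$paths$data_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 2L)
  base <- scene_from_config(cfg, seeds[1])
  train <- make_dataset(cfg$dataset$n_train,
    viability_range = cfg$dataset$viability_range,
    density_range = cfg$dataset$density_range,
    base_config = base, seed = seeds[1]
  )
  train$image_id <- sprintf("train_%03d", seq_len(nrow(train)))
  man_train <- write_fixture(train, file.path(cfg$paths$data_dir, "train"))
  man_val <- NULL
  if (cfg$dataset$n_val > 0) {
    val <- make_dataset(cfg$dataset$n_val,
      viability_range = cfg$dataset$viability_range,
      density_range = cfg$dataset$density_range,
      base_config = base, seed = seeds[2]
    )
    val$image_id <- sprintf("val_%03d", seq_len(nrow(val)))
    man_val <- write_fixture(val, file.path(cfg$paths$data_dir, "val"))
  }
  write_run_config(cfg, file.path(cfg$paths$data_dir, "config.yaml"))
  invisible(list(train = man_train, val = man_val))
}

# Per-image labelled, enhanced training tiles for one branch/target.
branch_tiles <- function(fixture, spec, target, tile_size) {
  rows <- purrr::map(seq_len(nrow(fixture)), function(i) {
    img <- fixture$image[[i]]
    ann <- fixture$annotations[[i]]
    tiles <- prepare_image(img, spec, tile_size)
    labels <- assign_labels(
      tile_image(to_grayscale(img), tile_size), ann,
      tile_size
    )
    df <- dplyr::inner_join(tiles, labels, by = c("image_id", "i", "j"))
    df$viability <- fixture$viability_truth_pct[i]
    df
  })
  dplyr::bind_rows(rows)
}

mode_targets <- function(mode) {
  switch(mode,
    dual_enhanced = c("total", "dead"),
    dual_plain = c("total", "dead"),
    single_direct = "viability_direct"
  )
}

target_branch <- function(target) {
  switch(target,
    total = "total",
    dead = "dead",
    viability_direct = "total"
  )
}

#' Train the counters of the configured variant
#'
#' Loads the generated fixture, builds the enhanced labelled tiles for each
#' branch, trains one or two counters, and writes checkpoints, a per-epoch
#' training-log CSV, the resolved config, and a log file into the run
#' directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of trained `cell_counter` models.
#' @export
cmd_train <- function(config) {
  cfg <- config
  man_train <- file.path(cfg$paths$data_dir, "train", "manifest.csv")
  if (!file.exists(man_train)) {
    abort(sprintf(
      "No training fixture at '%s'; run cmd_generate() first.", man_train
    ))
  }
  fixture <- read_fixture(man_train)
  man_val <- file.path(cfg$paths$data_dir, "val", "manifest.csv")
  val_fixture <- if (file.exists(man_val)) read_fixture(man_val)

  dir <- file.path(run_dir(cfg), "checkpoints")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rd <- dirname(dir)
  write_run_config(cfg, file.path(rd, "config.yaml"))
  log_line(rd, "training mode '%s' on %d images (seed %d)", cfg$mode, nrow(fixture), cfg$seed)

  seeds <- derive_seeds(cfg$seed, 4L)
  models <- list()
  logs <- list()
  for (k in seq_along(mode_targets(cfg$mode))) {
    target <- mode_targets(cfg$mode)[k]
    spec <- branch_spec(cfg, target_branch(target))
    data <- branch_tiles(fixture, spec, target, cfg$tile_size)
    val_data <- if (!is.null(val_fixture)) {
      branch_tiles(val_fixture, spec, target, cfg$tile_size)
    }
    model <- build_counter(target,
      channels = cfg$train$channels,
      stem_pool = cfg$train$stem_pool, tile_size = cfg$tile_size,
      seed = seeds[k]
    )
    model <- train_counter(model, data,
      training_config(
        epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
        lr = cfg$train$lr, augment = cfg$train$augment, seed = seeds[k] + 1L
      ),
      val_data = val_data
    )
    save_counter(model, file.path(dir, paste0(target, ".rds")))
    log_line(
      rd, "trained %s counter: final train mse %.3f", target,
      model$history$train_loss[nrow(model$history)]
    )
    h <- model$history
    h$target <- target
    logs[[target]] <- h
    models[[target]] <- model
  }
  write.csv(dplyr::bind_rows(logs), file.path(rd, "training_log.csv"),
    row.names = FALSE
  )
  invisible(models)
}

load_run_models <- function(cfg) {
  dir <- file.path(run_dir(cfg), "checkpoints")
  targets <- mode_targets(cfg$mode)
  paths <- file.path(dir, paste0(targets, ".rds"))
  if (!all(file.exists(paths))) {
    abort(sprintf(
      "Missing checkpoint(s) under '%s'; run cmd_train() first.", dir
    ))
  }
  setNames(purrr::map(paths, load_counter), targets)
}

predict_one_image <- function(cfg, models, image) {
  id <- image_id_of(image)
  if (cfg$mode == "single_direct") {
    v <- predict_image(
      models$viability_direct, image,
      branch_spec(cfg, "total")
    )$image_total
    return(tibble::tibble(
      image_id = id, T_hat = NA_real_, D_hat = NA_real_, V_hat = v
    ))
  }
  t_hat <- predict_image(models$total, image, branch_spec(cfg, "total"))$image_total
  d_hat <- predict_image(models$dead, image, branch_spec(cfg, "dead"))$image_total
  tibble::tibble(
    image_id = id, T_hat = t_hat, D_hat = d_hat,
    V_hat = combine_viability(t_hat, d_hat)
  )
}

#' Predict viability for a set of images
#'
#' Runs the enhancement-paired inference for every image and combines counts
#' into viability. Unreadable files produce a per-file warning and are
#' reported in the `failed` attribute; the run continues.
#'
#' @param config A [run_config()].
#' @param images Character vector of image paths, or a directory of PNGs.
#' @return A tibble with one row per successfully processed image
#'   (`image_id`, `T_hat`, `D_hat`, `V_hat`), with attribute `failed` naming
#'   the files that could not be processed.
#' @export
cmd_predict <- function(config, images) {
  cfg <- config
  models <- load_run_models(cfg)
  if (length(images) == 1 && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.png$", full.names = TRUE)
  }
  if (length(images) == 0) abort("No images to predict.")
  rows <- list()
  failed <- character(0)
  for (p in images) {
    row <- tryCatch(
      predict_one_image(cfg, models, read_image(p)),
      error = function(e) {
        warn(sprintf("Skipping '%s': %s", p, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(row)) failed <- c(failed, p) else rows[[length(rows) + 1L]] <- row
  }
  out <- dplyr::bind_rows(rows)
  rd <- run_dir(cfg)
  if (dir.exists(rd)) {
    write.csv(out, file.path(rd, "predictions.csv"), row.names = FALSE)
  }
  attr(out, "failed") <- failed
  out
}

#' Evaluate the trained variant on the validation fixture
#'
#' Predicts every validation image, combines counts into viability, compares
#' against the label-derived truth, and writes the report (CSV + JSON
#' summary) and predicted-vs-truth plots into the run directory. Per-image
#' count truths are summed over the tiled region (tile labels are the ground
#' truth the counters are scored on); the viability truth uses the full
#' annotation set.
#'
#' @param config A [run_config()].
#' @return The [evaluate_viability()] object, invisibly.
#' @export
cmd_evaluate <- function(config) {
  cfg <- config
  man_val <- file.path(cfg$paths$data_dir, "val", "manifest.csv")
  if (!file.exists(man_val)) {
    abort(sprintf("No validation fixture at '%s'.", man_val))
  }
  fixture <- read_fixture(man_val)
  if (nrow(fixture) == 0) abort("Validation set is empty.")
  models <- load_run_models(cfg)
  rows <- purrr::map(seq_len(nrow(fixture)), function(i) {
    pred <- predict_one_image(cfg, models, fixture$image[[i]])
    ann <- fixture$annotations[[i]]
    pred$image_id <- fixture$image_id[i]
    # count truths over the tiled (covered) region — the labels the counters
    # are trained and scored on; margin points never reach a tile
    labels <- suppressMessages(assign_labels(
      tile_image(to_grayscale(fixture$image[[i]]), cfg$tile_size), ann,
      cfg$tile_size
    ))
    pred$T_truth <- sum(labels$count_total)
    pred$D_truth <- sum(labels$count_dead)
    pred$V_truth <- truth_viability(ann)
    pred
  })
  results <- dplyr::bind_rows(rows)
  if (cfg$mode == "single_direct") {
    results$T_hat <- NULL
    results$D_hat <- NULL
    results$T_truth <- NULL
    results$D_truth <- NULL
  }
  ev <- evaluate_viability(results)
  rd <- run_dir(cfg)
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  write.csv(results, file.path(rd, "report.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(glance(ev)), file.path(rd, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  plot_paths <- file.path(rd, "predicted_vs_truth.png")
  ggplot2::ggsave(plot_paths, autoplot(ev), width = 9, height = 3.5, dpi = 120)
  log_line(rd, "evaluated %d images: viability MAE %.2f pp", nrow(results), ev$viability$mae)
  invisible(ev)
}

#' Compare the three model variants on one synthetic corpus
#'
#' Trains and evaluates each requested variant with the same fixture and
#' seeds and returns a side-by-side summary. This reproduces the qualitative
#' comparison between the direct single-network baseline, the unenhanced
#' dual-counter setup, and the enhancement-paired dual-counter method.
#'
#' @param config A [run_config()]; its fixture must already exist (or is
#'   generated on the fly when missing).
#' @param modes Character vector of variants to run.
#' @return A tibble with one row per mode (viability MAE/bias etc.).
#' @export
compare_variants <- function(config,
                             modes = c("dual_enhanced", "single_direct")) {
  cfg <- config
  if (!file.exists(file.path(cfg$paths$data_dir, "train", "manifest.csv"))) {
    cmd_generate(cfg)
  }
  rows <- purrr::map(modes, function(m) {
    sub <- cfg
    sub$mode <- m
    sub$run_id <- paste0(cfg$run_id %||% "run", "_", m)
    cmd_train(sub)
    g <- glance(cmd_evaluate(sub))
    g$mode <- m
    g
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("mode")
}
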