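# Count-regression counters: build, train, predict, save/load.

#' Build a count-regression counter
#'
#' All three model variants — the total-cell counter, the dead-cell counter
#' and the direct-viability baseline — share one architecture: a small
#' convolutional backbone, global average pooling, and a fully connected
#' layer with a single neuron emitting one scalar per tile. They differ only
#' in target semantics (and in which enhancement their tiles receive):
#' count targets are reported as `max(0, raw)`, the direct-viability target
#' is clamped to 0..100.
#'
#' The default backbone is a deliberately small stack (a 2x average-pooling
#' stem, then `n_stages` stride-2 3x3 conv + ReLU blocks) sized for CPU
#' training on synthetic corpora. `pretrained_init` exists for transfer
#' learning from locally available weights; requesting it without a weights
#' file is an error — nothing is ever downloaded.
#'
#' @param target `"total"`, `"dead"`, or `"viability_direct"`.
#' @param channels Integer vector: output channels of each conv stage.
#' @param stem_pool Input down-scaling factor (power of 2) applied before the
#'   first convolution.
#' @param tile_size Expected tile edge (default 224).
#' @param pretrained_init Initialise from `pretrained_weights` instead of
#'   random weights.
#' @param pretrained_weights Path to a local checkpoint whose parameters
#'   match `channels`.
#' @param seed Seed for weight initialisation; same seed and config give
#'   identical initial weights.
#' @return An object of class `cell_counter`.
#' @examples
#' m <- build_counter("total", channels = c(4, 8), seed = 1)
#' predict_tile(m, matrix(0, 224, 224))
#' @export
build_counter <- function(target = c("total", "dead", "viability_direct"),
                          channels = c(8, 16, 32, 32), stem_pool = 2L,
                          tile_size = 224L, pretrained_init = FALSE,
                          pretrained_weights = NULL, seed = 1L) {
  target <- match.arg(target)
  if (length(channels) < 1 || any(channels < 1)) {
    abort("`channels` must give at least one positive stage width.")
  }
  if (!stem_pool %in% c(1L, 2L, 4L)) {
    abort("`stem_pool` must be 1, 2 or 4.")
  }
  backbone <- list(
    n_stages = length(channels), channels = as.integer(channels),
    kernel = 3L, stride = 2L, pad = 1L, stem_pool = as.integer(stem_pool),
    pretrained_init = isTRUE(pretrained_init)
  )
  input_spec <- list(
    size = as.integer(tile_size), channels = 1L,
    scale = 255, offset = 0
  )
  if (isTRUE(pretrained_init)) {
    if (is.null(pretrained_weights) || !file.exists(pretrained_weights)) {
      abort(paste(
        "`pretrained_init = TRUE` requires a local `pretrained_weights`",
        "checkpoint; weights are never downloaded."
      ))
    }
    donor <- load_counter(pretrained_weights)
    if (!identical(donor$backbone$channels, backbone$channels)) {
      abort("Pretrained checkpoint does not match the requested `channels`.")
    }
    params <- donor$params
  } else {
    params <- nn_init_params(backbone, seed)
  }
  structure(
    list(
      target = target, backbone = backbone, input_spec = input_spec,
      params = params, history = tibble::tibble(
        epoch = integer(),
        train_loss = numeric(), val_loss = numeric()
      ),
      trained = FALSE, seed = as.integer(seed)
    ),
    class = "cell_counter"
  )
}

#' @export
print.cell_counter <- function(x, ...) {
  cat(sprintf(
    "<cell_counter> target = %s | %d conv stage(s) (%s), stem pool %dx | %d parameters | %s\n",
    x$target, x$backbone$n_stages, paste(x$backbone$channels, collapse = "-"),
    x$backbone$stem_pool, nn_n_params(x$params),
    if (x$trained) sprintf("trained (%d epochs)", max(x$history$epoch)) else "untrained"
  ))
  invisible(x)
}

target_column <- function(target) {
  switch(target,
    total = "count_total",
    dead = "count_dead",
    viability_direct = "viability"
  )
}

#' Configure a training run
#'
#' Squared-error loss on the scalar output, optimised with Adam. None of the
#' budget parameters are baked into the models; everything that matters is
#' here. Weights are never frozen during training (`freeze_policy` is fixed
#' at `"none"`).
#'
#' @param epochs Number of passes over the training tiles (>= 1).
#' @param batch_size Tiles per gradient step (>= 1).
#' @param lr Adam learning rate.
#' @param augment Apply a random flip/rotation (count-preserving) to each
#'   tile per epoch.
#' @param seed Seed for shuffling/augmentation.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 10L, batch_size = 4L, lr = 5e-3,
                            augment = TRUE, seed = 1L) {
  if (!is_count(epochs) || epochs < 1) abort("`epochs` must be >= 1.")
  if (!is_count(batch_size) || batch_size < 1) abort("`batch_size` must be >= 1.")
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, optimizer = "adam", loss = "mse", augment = isTRUE(augment),
      freeze_policy = "none", seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

counter_training_frame <- function(model, data) {
  col <- target_column(model$target)
  if (!all(c("pixels", col) %in% names(data))) {
    abort(sprintf(
      "Training data for a '%s' counter needs columns `pixels` and `%s`.",
      model$target, col
    ))
  }
  sz <- model$input_spec$size
  ok <- purrr::map_lgl(data$pixels, ~ is.matrix(.x) &&
    nrow(.x) == sz && ncol(.x) == sz)
  if (!all(ok)) {
    abort(sprintf("All tiles must be %d x %d grayscale matrices.", sz, sz))
  }
  list(tiles = data$pixels, y = as.numeric(data[[col]]))
}

#' Train a counter on labelled tiles
#'
#' Mini-batch Adam on the mean squared error between the scalar output and
#' the tile label (`count_total`, `count_dead`, or the parent image's
#' viability percentage for the direct baseline). The output bias is
#' initialised to the mean training target before the first step, a standard
#' shortcut for regression heads. All weights train; none are frozen.
#'
#' @param model A [build_counter()] model.
#' @param data Tibble with a `pixels` list-column of enhanced tiles and the
#'   label column matching `model$target` (see [assign_labels()]).
#' @param config A [training_config()].
#' @param val_data Optional tibble like `data`, evaluated once per epoch.
#' @param quiet Suppress the per-epoch progress message.
#' @return The trained model; `$history` holds one row per epoch with
#'   `train_loss` (and `val_loss` when `val_data` is given).
#' @export
train_counter <- function(model, data, config = training_config(),
                          val_data = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "cell_counter"))
  if (nrow(data) == 0) abort("Training set is empty.")
  tf <- counter_training_frame(model, data)
  vf <- if (!is.null(val_data)) counter_training_frame(model, val_data)
  n <- length(tf$tiles)
  params <- model$params
  if (!model$trained) params$head$b <- mean(tf$y)
  opt <- adam_init(params)
  hist <- list()

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      orients <- if (config$augment) sample(0:7, n, replace = TRUE) else rep(0L, n)
      ep_loss <- 0
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        bs <- length(idx)
        acc <- nn_grad_zero(params)
        for (ii in seq_along(idx)) {
          tile <- tf$tiles[[idx[ii]]]
          if (config$augment) tile <- orient_tile(tile, orients[idx[ii]])
          fwd <- nn_forward(params, tile, model$backbone, model$input_spec,
            keep_cache = TRUE
          )
          err <- fwd$pred - tf$y[idx[ii]]
          ep_loss <- ep_loss + err^2
          acc <- nn_grad_add(
            acc,
            nn_backward(params, fwd, 2 * err / bs, model$backbone)
          )
        }
        st <- adam_step(params, acc, opt, config$lr)
        params <- st$params
        opt <- st$state
      }
      row <- tibble::tibble(epoch = epoch, train_loss = ep_loss / n)
      row$val_loss <- if (!is.null(vf)) {
        mean(purrr::map_dbl(seq_along(vf$tiles), function(i) {
          (nn_forward(params, vf$tiles[[i]], model$backbone,
            model$input_spec)$pred - vf$y[i])^2
        }))
      } else {
        NA_real_
      }
      hist[[epoch]] <- row
      if (!quiet) {
        inform(sprintf(
          "epoch %d/%d  train_mse = %.3f%s", epoch, config$epochs,
          row$train_loss,
          if (!is.na(row$val_loss)) sprintf("  val_mse = %.3f", row$val_loss) else ""
        ))
      }
    }
  })

  model$params <- params
  model$history <- dplyr::bind_rows(model$history, dplyr::bind_rows(hist))
  model$trained <- TRUE
  model$training_config <- config
  model
}

clamp_prediction <- function(raw, target) {
  if (target == "viability_direct") clamp(raw, 0, 100) else pmax(raw, 0)
}

#' Predict the count for one tile
#'
#' The caller is responsible for feeding the enhancement the model was
#' trained with (contrast-stretched tiles for the total counter, Sobel tiles
#' for the dead counter; identity for the unenhanced ablations).
#'
#' @param model A `cell_counter`.
#' @param tile A `size x size` grayscale matrix (0..255).
#' @return A single non-negative number (0..100 for the direct-viability
#'   baseline).
#' @export
predict_tile <- function(model, tile) {
  stopifnot(inherits(model, "cell_counter"))
  sz <- model$input_spec$size
  if (!is.matrix(tile) || nrow(tile) != sz || ncol(tile) != sz) {
    abort(sprintf("`tile` must be a %d x %d grayscale matrix.", sz, sz))
  }
  raw <- nn_forward(model$params, tile, model$backbone, model$input_spec)$pred
  clamp_prediction(raw, model$target)
}

#' Predict per-tile counts over a tile tibble
#'
#' @param model A `cell_counter`.
#' @param tiles A tibble from [tile_image()] / [prepare_image()] whose
#'   `pixels` already carry the model's enhancement.
#' @return `tiles` (minus `pixels`) with a `.pred` column.
#' @export
predict_tiles <- function(model, tiles) {
  preds <- purrr::map_dbl(tiles$pixels, ~ predict_tile(model, .x))
  out <- dplyr::select(tiles, -"pixels")
  out$.pred <- preds
  out
}

#' Predict an image-level count
#'
#' Enhances and tiles a full frame (via [prepare_image()]), predicts every
#' tile, and aggregates: count targets sum over tiles (an image's count is
#' the sum of its tiles' counts); the direct-viability baseline averages its
#' per-tile percentages instead.
#'
#' @param model A `cell_counter`.
#' @param image Image matrix or array.
#' @param enhancement An [enhancement_spec()]; pair `contrast` with the total
#'   counter and `sobel` with the dead counter (identity reproduces the
#'   unenhanced ablation).
#' @return A list with `per_tile` (tibble of tile predictions, row-major) and
#'   `image_total` (the aggregate).
#' @export
predict_image <- function(model, image, enhancement = enhancement_spec("identity")) {
  tiles <- prepare_image(image, enhancement, model$input_spec$size)
  per_tile <- predict_tiles(model, tiles)
  agg <- if (model$target == "viability_direct") {
    mean(per_tile$.pred)
  } else {
    sum(per_tile$.pred)
  }
  list(per_tile = per_tile, image_total = agg)
}

#' Save / load a counter checkpoint
#'
#' The checkpoint is a single RDS file holding weights, architecture, input
#' spec and training history; `load_counter()` restores a model whose
#' predictions are bit-identical to the saved one.
#'
#' @param model A `cell_counter`.
#' @param path Checkpoint path.
#' @return `save_counter()`: `path` invisibly; `load_counter()`: the model.
#' @export
save_counter <- function(model, path) {
  stopifnot(inherits(model, "cell_counter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_counter
#' @export
load_counter <- function(path) {
  if (!file.exists(path)) abort(sprintf("Checkpoint '%s' does not exist.", path))
  model <- readRDS(path)
  if (!inherits(model, "cell_counter")) {
    abort(sprintf("'%s' is not a cell_counter checkpoint.", path))
  }
  model
}

#' Tidy a fitted counter
#'
#' `tidy()` returns the per-epoch loss history; `glance()` a one-row summary
#' (target, parameter count, epochs, final losses).
#'
#' @param x A `cell_counter`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cell_counter
#' @export
tidy.cell_counter <- function(x, ...) {
  x$history
}

#' @rdname tidy.cell_counter
#' @method glance cell_counter
#' @export
glance.cell_counter <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_params = nn_n_params(x$params),
    n_stages = x$backbone$n_stages,
    trained = x$trained,
    epochs = if (nrow(x$history)) max(x$history$epoch) else 0L,
    final_train_loss = if (nrow(x$history)) {
      x$history$train_loss[nrow(x$history)]
    } else {
      NA_real_
    },
    final_val_loss = if (nrow(x$history)) {
      x$history$val_loss[nrow(x$history)]
    } else {
      NA_real_
    }
  )
}

#' Plot a counter's training curve
#'
#' @param object A trained `cell_counter`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cell_counter
#' @export
autoplot.cell_counter <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "series", values_to = "mse"
  )
  h <- h[!is.na(h$mse), ]
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mse, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "epoch", y = "mean squared error",
      title = sprintf("Training curve (%s counter)", object$target)
    ) +
    ggplot2::theme_minimal()
}
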