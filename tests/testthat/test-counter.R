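# Counter models: architecture parity, gradients, training behaviour,
# prediction contracts and serialization.

test_that("total and dead counters share one architecture", {
  tot <- build_counter("total", seed = 1)
  dead <- build_counter("dead", seed = 1)
  shapes <- function(m) purrr::map(m$params$conv, ~ dim(.x$w))
  expect_identical(shapes(tot), shapes(dead))
  expect_identical(
    brightcount:::nn_n_params(tot$params),
    brightcount:::nn_n_params(dead$params)
  )
  # same seed, same config => identical initial weights
  expect_identical(tot$params, build_counter("total", seed = 1)$params)
  expect_false(identical(tot$params, build_counter("total", seed = 2)$params))
})

test_that("a forward pass on a zero tile yields one finite scalar, deterministically", {
  m <- build_counter("total", channels = c(4, 8), seed = 3)
  z <- matrix(0, 224, 224)
  p1 <- predict_tile(m, z)
  expect_length(p1, 1)
  expect_true(is.finite(p1))
  expect_gte(p1, 0)
  expect_identical(p1, predict_tile(m, z))
  expect_error(predict_tile(m, matrix(0, 100, 100)), "224 x 224")
})

test_that("count predictions are non-negative and direct viability stays in 0..100", {
  withr::with_seed(4, tile <- matrix(runif(224^2, 0, 255), 224, 224))
  for (target in c("total", "dead")) {
    m <- build_counter(target, channels = c(2, 4), seed = 5)
    expect_gte(predict_tile(m, tile), 0)
  }
  mv <- build_counter("viability_direct", channels = c(2, 4), seed = 5)
  p <- predict_tile(mv, tile)
  expect_gte(p, 0)
  expect_lte(p, 100)
})

test_that("pretrained initialisation requires a local weights file", {
  expect_error(
    build_counter("total", pretrained_init = TRUE),
    "never downloaded"
  )
})

test_that("analytic gradients match numerical differentiation", {
  # tiny network + tile so central differences are cheap and stable
  model <- build_counter("total",
    channels = c(2, 3), stem_pool = 1L,
    tile_size = 12L, seed = 8
  )
  withr::with_seed(9, tile <- matrix(runif(144, 0, 255), 12, 12))
  y <- 3
  loss_of <- function(params) {
    (brightcount:::nn_forward(
      params, tile, model$backbone,
      model$input_spec
    )$pred - y)^2
  }
  fwd <- brightcount:::nn_forward(model$params, tile, model$backbone,
    model$input_spec,
    keep_cache = TRUE
  )
  gr <- brightcount:::nn_backward(
    model$params, fwd, 2 * (fwd$pred - y),
    model$backbone
  )
  eps <- 1e-6
  num_grad <- function(get, set) {
    p <- model$params
    v <- get(p)
    g <- numeric(length(v))
    for (k in seq_along(v)) {
      up <- v
      up[k] <- v[k] + eps
      dn <- v
      dn[k] <- v[k] - eps
      g[k] <- (loss_of(set(p, up)) - loss_of(set(p, dn))) / (2 * eps)
    }
    g
  }
  # conv layer 1 weights
  g1 <- num_grad(
    function(p) as.vector(p$conv[[1]]$w),
    function(p, v) {
      p$conv[[1]]$w <- matrix(v, nrow(p$conv[[1]]$w))
      p
    }
  )
  expect_equal(as.vector(gr$conv[[1]]$w), g1, tolerance = 1e-5)
  # conv layer 2 bias
  g2 <- num_grad(
    function(p) p$conv[[2]]$b,
    function(p, v) {
      p$conv[[2]]$b <- v
      p
    }
  )
  expect_equal(gr$conv[[2]]$b, g2, tolerance = 1e-5)
  # head
  gh <- num_grad(
    function(p) p$head$w,
    function(p, v) {
      p$head$w <- v
      p
    }
  )
  expect_equal(gr$head$w, gh, tolerance = 1e-5)
})

test_that("training reduces the loss and records one history row per epoch", {
  data <- toy_tiles(40, seed = 31)
  m <- build_counter("total", channels = c(4, 8), tile_size = 64L, seed = 32)
  cfg <- training_config(epochs = 5, batch_size = 8, lr = 5e-3, seed = 33)
  fit <- train_counter(m, data, cfg)
  expect_equal(nrow(fit$history), 5)
  expect_lte(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_true(fit$trained)
  # reproducible under identical seeds
  fit2 <- train_counter(m, data, cfg)
  expect_identical(fit$history$train_loss, fit2$history$train_loss)
})

test_that("training on a constant-label set converges toward that constant", {
  data <- toy_tiles(30, seed = 41)
  data$count_total <- 4L
  m <- build_counter("total", channels = c(4, 8), tile_size = 64L, seed = 42)
  fit <- train_counter(
    m, data,
    training_config(epochs = 6, batch_size = 8, lr = 5e-3, seed = 43)
  )
  preds <- purrr::map_dbl(data$pixels, ~ predict_tile(fit, .x))
  expect_lt(mean(abs(preds - 4)), 0.5)
})

test_that("empty sets and mismatched labels are rejected", {
  m <- build_counter("dead", channels = c(2, 4), tile_size = 64L)
  expect_error(train_counter(m, toy_tiles(0)), "empty|count_dead")
  expect_error(train_counter(m, toy_tiles(5)), "count_dead")
})

test_that("checkpoints round-trip with bit-identical predictions", {
  data <- toy_tiles(20, seed = 51)
  m <- train_counter(
    build_counter("total", channels = c(4, 8), tile_size = 64L, seed = 52),
    data, training_config(epochs = 2, batch_size = 8, seed = 53)
  )
  f <- withr::local_tempfile(fileext = ".rds")
  save_counter(m, f)
  back <- load_counter(f)
  tile <- data$pixels[[1]]
  expect_identical(predict_tile(back, tile), predict_tile(m, tile))
  expect_identical(back$history, m$history)
  expect_error(load_counter(tempfile()), "does not exist")
})

test_that("image predictions are the sum of row-major tile predictions", {
  m <- build_counter("total", channels = c(2, 4), seed = 61)
  img <- render_scene(small_scene(seed = 62, width = 672, height = 448))$image
  res <- predict_image(m, img, enhancement_spec("contrast"))
  expect_equal(nrow(res$per_tile), 6)
  expect_equal(res$image_total, sum(res$per_tile$.pred))
  # additivity against independent per-tile calls
  tiles <- prepare_image(img, enhancement_spec("contrast"))
  indep <- sum(purrr::map_dbl(tiles$pixels, ~ predict_tile(m, .x)))
  expect_equal(res$image_total, indep)
  expect_error(
    predict_image(m, matrix(0, 100, 100)),
    "smaller than"
  )
})

test_that("tidy and glance summarise fitted counters", {
  data <- toy_tiles(16, seed = 71)
  m <- train_counter(
    build_counter("total", channels = c(2, 4), tile_size = 64L, seed = 72),
    data, training_config(epochs = 3, batch_size = 8, seed = 73)
  )
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  g <- glance(m)
  expect_equal(g$target, "total")
  expect_equal(g$epochs, 3L)
  expect_true(g$n_params > 0)
  expect_s3_class(autoplot(m), "ggplot")
})
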