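# Shared test fixtures: small scenes, tiny counters, and an independent
# brute-force Sobel oracle.

# A compact scene that still has both morphologies and artifacts.
small_scene <- function(seed = 1, n_live = 12, n_dead = 6, width = 448,
                        height = 448, n_artifacts = 2) {
  scene_config(
    width = width, height = height, n_live = n_live, n_dead = n_dead,
    n_artifacts = n_artifacts, seed = seed
  )
}

# Independent nested-loop Sobel with the same reflect (edge-duplicating)
# padding; used as the oracle for sobel_magnitude().
sobel_brute <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  refl <- function(i, n) min(max(i, 1L), n)
  wx <- c(-1, 0, 1)
  ws <- c(1, 2, 1)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      gx <- 0
      gy <- 0
      for (dy in -1:1) {
        for (dx in -1:1) {
          v <- m[refl(r + dy, h), refl(c + dx, w)]
          gx <- gx + wx[dx + 2] * ws[dy + 2] * v
          gy <- gy + ws[dx + 2] * wx[dy + 2] * v
        }
      }
      out[r, c] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# A toy counter + labelled-tile frame trained in seconds (64 px tiles).
toy_tiles <- function(n, size = 64L, value_fun = NULL, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      pixels = purrr::map(seq_len(n), function(i) {
        m <- matrix(round(runif(size * size, 100, 160)), size, size)
        storage.mode(m) <- "integer"
        m
      }),
      count_total = sample(0:5, n, replace = TRUE)
    )
  })
}

random_tile_matrix <- function(size = 224L, seed = 1) {
  withr::with_seed(seed, matrix(round(runif(size * size, 0, 255)), size, size))
}

expect_annotation_equal <- function(a, b) {
  testthat::expect_equal(a$x, b$x)
  testthat::expect_equal(a$y, b$y)
  testthat::expect_equal(a$cls, b$cls)
}
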