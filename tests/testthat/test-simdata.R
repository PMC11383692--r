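# Synthetic scene generator: count conservation, determinism, separation,
# morphological separability, dataset generation and fixture round-trips.

test_that("an empty scene is pure background with zero annotations", {
  sc <- render_scene(scene_config(
    width = 300, height = 200, n_live = 0,
    n_dead = 0, n_artifacts = 0, seed = 3
  ))
  expect_equal(dim(sc$image), c(200, 300))
  expect_equal(n_total(sc$annotations), 0)
  # noise only: intensities hug the background mean
  expect_lt(abs(mean(sc$image) - 130), 2)
  expect_gt(stats::sd(sc$image), 2)
})

test_that("annotations match the requested composition exactly", {
  cfg <- small_scene(seed = 7, n_live = 30, n_dead = 10, width = 672, height = 672)
  sc <- render_scene(cfg)
  expect_equal(n_live(sc$annotations), 30)
  expect_equal(n_dead(sc$annotations), 10)
  expect_equal(truth_viability(sc$annotations), 75.0)
  expect_equal(dim(sc$image), c(672, 672))
})

test_that("rendering is bit-identical under a fixed seed and config", {
  cfg <- small_scene(seed = 7)
  a <- render_scene(cfg)
  b <- render_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations$x, b$annotations$x)
  expect_false(identical(
    render_scene(small_scene(seed = 8))$image,
    a$image
  ))
})

test_that("no two object centres violate min_separation", {
  for (seed in 1:5) {
    sc <- render_scene(small_scene(seed = seed, n_live = 15, n_dead = 8))
    pts <- sc$annotations
    d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
    diag(d) <- Inf
    expect_gte(min(d), 26)
  }
})

test_that("impossible placements and invalid configs raise errors", {
  expect_error(
    render_scene(scene_config(
      width = 150, height = 150, n_live = 200,
      n_dead = 0, n_artifacts = 0
    )),
    "Could not place|too small"
  )
  expect_error(scene_config(width = 0), "positive")
  expect_error(scene_config(n_live = -1), "non-negative")
  expect_error(
    scene_config(
      width = 100, height = 100,
      live_shape = list(axis_range = c(30, 40), ecc_range = c(0.3, 0.6))
    ),
    "smaller than"
  )
})

test_that("dead cells respond more strongly to the Sobel filter than live cells", {
  # mean gradient magnitude in a disk around each centre, >= 20 seeded scenes
  disk_mean <- function(mag, x, y, r = 18) {
    h <- nrow(mag)
    w <- ncol(mag)
    vals <- purrr::map2_dbl(x, y, function(cx, cy) {
      rows <- max(1, cy + 1 - r):min(h, cy + 1 + r)
      cols <- max(1, cx + 1 - r):min(w, cx + 1 + r)
      dy <- outer(rows - (cy + 1), rep(1, length(cols)))
      dx <- outer(rep(1, length(rows)), cols - (cx + 1))
      mean(mag[rows, cols][dx^2 + dy^2 <= r^2])
    })
    mean(vals)
  }
  wins <- purrr::map_lgl(1:20, function(seed) {
    sc <- render_scene(small_scene(seed = seed, n_live = 10, n_dead = 6))
    mag <- sobel_magnitude(to_grayscale(sc$image))
    ann <- sc$annotations
    dead <- ann[ann$cls == "dead", ]
    live <- ann[ann$cls == "live", ]
    disk_mean(mag, dead$x, dead$y) > disk_mean(mag, live$x, live$y)
  })
  expect_true(all(wins))
})

test_that("make_dataset spans the requested viability range deterministically", {
  base <- small_scene()
  ds <- make_dataset(4,
    viability_range = c(13, 97), density_range = c(15, 25),
    base_config = base, seed = 42
  )
  expect_equal(nrow(ds), 4)
  expect_true(all(ds$viability_truth_pct >= 13 & ds$viability_truth_pct <= 97))
  expect_equal(ds$n_live + ds$n_dead, purrr::map_int(ds$annotations, n_total))

  ds2 <- make_dataset(4,
    viability_range = c(13, 97), density_range = c(15, 25),
    base_config = base, seed = 42
  )
  expect_identical(ds$image, ds2$image)

  all_live <- make_dataset(1,
    viability_range = c(100, 100),
    density_range = c(10, 10), base_config = base, seed = 1
  )
  expect_equal(all_live$n_dead, 0)
  expect_equal(all_live$viability_truth_pct, 100)
})

test_that("make_dataset rejects invalid arguments", {
  expect_error(make_dataset(0, base_config = small_scene()), "positive integer")
  expect_error(
    make_dataset(2, viability_range = c(90, 10), base_config = small_scene()),
    "viability_range"
  )
  expect_error(
    make_dataset(2, viability_range = c(-5, 50), base_config = small_scene()),
    "viability_range"
  )
})

test_that("write_fixture/read_fixture round-trips images and annotations exactly", {
  base <- small_scene(n_live = 8, n_dead = 4)
  ds <- make_dataset(2,
    viability_range = c(40, 80), density_range = c(10, 14),
    base_config = base, seed = 9
  )
  dir <- withr::local_tempdir()
  manifest <- write_fixture(ds, dir)
  expect_true(file.exists(manifest))
  man <- read.csv(manifest)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$json_path)))

  back <- read_fixture(manifest)
  for (i in 1:2) {
    expect_equal(
      unname(unclass(back$image[[i]])),
      unname(unclass(ds$image[[i]]))
    )
    expect_annotation_equal(back$annotations[[i]], ds$annotations[[i]])
  }
  expect_equal(back$viability_truth_pct, ds$viability_truth_pct)
})

test_that("an empty dataset writes an empty manifest and no files", {
  dir <- withr::local_tempdir()
  empty <- make_dataset(1,
    viability_range = c(50, 50), density_range = c(4, 4),
    base_config = small_scene()
  )[0, ]
  manifest <- write_fixture(empty, dir)
  expect_equal(nrow(read.csv(manifest)), 0)
  expect_length(list.files(dir, pattern = "\\.png$"), 0)
})

test_that("three-channel scenes replicate the grayscale plane", {
  cfg <- small_scene(seed = 5, n_live = 4, n_dead = 2, width = 256, height = 256)
  cfg$channels <- 3L
  sc <- render_scene(cfg)
  expect_equal(dim(sc$image), c(256, 256, 3))
  expect_equal(sc$image[, , 1], sc$image[, , 3])
})
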