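# Enhancements and tiling.

test_that("to_grayscale uses luminance weights and is the identity on grayscale", {
  v <- 120
  rgb_uniform <- array(v, dim = c(10, 12, 3))
  expect_equal(unclass(to_grayscale(rgb_uniform)), matrix(v, 10, 12))

  g <- matrix(7, 5, 5)
  expect_identical(unname(unclass(to_grayscale(g))), unname(g))

  red <- array(0, dim = c(4, 4, 3))
  red[, , 1] <- 200
  blue <- array(0, dim = c(4, 4, 3))
  blue[, , 3] <- 200
  expect_equal(to_grayscale(red)[1, 1], round(0.299 * 200))
  expect_equal(to_grayscale(blue)[1, 1], round(0.114 * 200))
  expect_error(to_grayscale(array(0, dim = c(4, 4, 2))), "matrix|array")
})

test_that("contrast stretch maps percentile anchors to 0 and 255", {
  # full-range image under a 0-100 stretch is unchanged
  m <- matrix(round(seq(0, 255, length.out = 64)), 8, 8)
  out <- enhance_contrast(m, p_low = 0, p_high = 100)
  expect_equal(unclass(out), unname(m))

  # two-level image: closed-form linear map
  two <- matrix(rep(c(100, 150), each = 8), 4, 4)
  out2 <- enhance_contrast(two, p_low = 0, p_high = 100)
  expect_setequal(unique(as.vector(out2)), c(0, 255))

  # constant image: documented degenerate rule
  expect_warning(z <- enhance_contrast(matrix(80, 6, 6)), "Constant image")
  expect_true(all(z == 0))
})

test_that("contrast stretch is monotone in pixel intensity", {
  withr::with_seed(11, {
    for (k in 1:5) {
      m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
      out <- enhance_contrast(m)
      o <- order(as.vector(m))
      expect_true(all(diff(as.vector(out)[o]) >= 0))
    }
  })
})

test_that("Sobel magnitude matches a brute-force nested-loop convolution", {
  withr::with_seed(5, {
    for (k in 1:10) {
      h <- sample(4:32, 1)
      w <- sample(4:32, 1)
      m <- matrix(runif(h * w, 0, 255), h, w)
      expect_equal(sobel_magnitude(m), sobel_brute(m), tolerance = 1e-12)
    }
  })
})

test_that("Sobel of a constant image is zero and a step edge peaks at the edge", {
  expect_true(all(enhance_sobel(matrix(42, 16, 16)) == 0))

  step <- cbind(matrix(0, 8, 4), matrix(255, 8, 4))
  mag <- sobel_magnitude(step)
  expect_true(all(mag[, 4:5] == max(mag)))
  expect_true(all(mag[, c(1:2, 7:8)] == 0))
})

test_that("Sobel magnitude commutes with 90-degree rotation", {
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  withr::with_seed(6, m <- matrix(runif(20 * 30, 0, 255), 20, 30))
  expect_equal(sobel_magnitude(rot90(m)), rot90(sobel_magnitude(m)),
    tolerance = 1e-12
  )
})

test_that("enhance_sobel rescales to the full 8-bit range", {
  withr::with_seed(7, m <- matrix(round(runif(900, 0, 255)), 30, 30))
  out <- enhance_sobel(m)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
})

test_that("tiling reproduces the printed grid arithmetic", {
  frame <- matrix(0L, 1536, 2048) # H x W
  tiles <- tile_image(frame)
  expect_equal(nrow(tiles), 54)
  expect_equal(max(tiles$i) + 1, 9)
  expect_equal(max(tiles$j) + 1, 6)

  expect_equal(nrow(tile_image(matrix(0L, 224, 224))), 1)

  t6 <- tile_image(matrix(0L, 448, 672)) # 672 wide x 448 high -> 3 x 2
  expect_equal(nrow(t6), 6)
  # row-major ordering with origins at multiples of 224
  expect_equal(t6$i, rep(0:2, times = 2))
  expect_equal(t6$j, rep(0:1, each = 3))
  expect_equal(t6$x0, t6$i * 224L)
  expect_equal(t6$y0, t6$j * 224L)

  expect_error(tile_image(matrix(0L, 100, 500)), "smaller than")
})

test_that("tile count equals the exhaustive grid for random sizes and tiles reassemble the covered region", {
  withr::with_seed(21, {
    for (k in 1:8) {
      h <- sample(224:800, 1)
      w <- sample(224:800, 1)
      img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
      tiles <- tile_image(img)
      # oracle: exhaustively enumerate non-overlapping anchored placements
      expect_equal(nrow(tiles), length(seq(1, w - 223, by = 224)) *
        length(seq(1, h - 223, by = 224)))
      # disjoint + complete: rebuild and compare with the covered crop
      rebuilt <- matrix(NA_integer_, (h %/% 224) * 224, (w %/% 224) * 224)
      for (r in seq_len(nrow(tiles))) {
        rows <- (tiles$y0[r] + 1):(tiles$y0[r] + 224)
        cols <- (tiles$x0[r] + 1):(tiles$x0[r] + 224)
        expect_true(all(is.na(rebuilt[rows, cols]))) # pairwise disjoint
        rebuilt[rows, cols] <- tiles$pixels[[r]]
      }
      expect_false(anyNA(rebuilt))
      expect_equal(rebuilt, img[seq_len(nrow(rebuilt)), seq_len(ncol(rebuilt))])
    }
  })
})

test_that("points map to tiles by the half-open grid convention", {
  img <- matrix(0L, 1536, 2048)
  tiles <- tile_image(img)
  set <- annotation_set(
    x = c(0, 223, 224, 2047, 10),
    y = c(0, 223, 224, 10, 1400),
    cls = rep("live", 5), image_id = "image"
  )
  expect_message(labels <- assign_labels(tiles, set), "dropped")
  expect_equal(attr(labels, "dropped"), 2) # x = 2047 and y = 1400 margins
  expect_equal(labels$count_total[labels$i == 0 & labels$j == 0], 2L)
  expect_equal(labels$count_total[labels$i == 1 & labels$j == 1], 1L)
  expect_equal(sum(labels$count_total) + attr(labels, "dropped"), 5)
})

test_that("label assignment conserves annotations across random scenes", {
  for (seed in 1:6) {
    sc <- render_scene(small_scene(
      seed = seed, n_live = 20, n_dead = 10,
      width = 500, height = 460
    ))
    tiles <- tile_image(to_grayscale(sc$image))
    labels <- suppressMessages(assign_labels(tiles, sc$annotations))
    expect_equal(
      sum(labels$count_total) + attr(labels, "dropped"),
      n_total(sc$annotations)
    )
    expect_true(all(labels$count_dead <= labels$count_total))
    expect_equal(sum(labels$count_dead <= n_dead(sc$annotations)), nrow(labels))
  }
})

test_that("assign_labels refuses tiles from mixed parent images", {
  a <- tile_image(matrix(0L, 224, 224))
  b <- a
  b$image_id <- "other"
  mixed <- dplyr::bind_rows(a, b)
  set <- annotation_set(1, 1, "live")
  expect_error(assign_labels(mixed, set), "single parent")
})

test_that("prepare_image pairs each enhancement with its tiling convention", {
  sc <- render_scene(small_scene(seed = 3, width = 448, height = 448))
  raw <- tile_image(to_grayscale(sc$image))

  ct <- prepare_image(sc$image, enhancement_spec("contrast"))
  expect_equal(nrow(ct), 4)
  # per-image stretch: tiles are crops of the stretched frame
  stretched <- enhance_contrast(to_grayscale(sc$image))
  expect_equal(ct$pixels[[1]], stretched[1:224, 1:224])

  sb <- prepare_image(sc$image, enhancement_spec("sobel"))
  # per-tile Sobel: first tile equals enhance_sobel of the raw first tile
  expect_equal(sb$pixels[[1]], enhance_sobel(raw$pixels[[1]]))

  id <- prepare_image(sc$image, enhancement_spec("identity"))
  expect_equal(id$pixels[[2]], raw$pixels[[2]])
})
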