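# Image input/output, the two enhancements, and 224x224 tiling.
#
# Images are numeric H x W matrices (grayscale) or H x W x 3 arrays with
# 8-bit intensities (0..255) and an `image_id` attribute. Pixel coordinates
# in annotations are 0-based with x = column, y = row.

#' Read / write 8-bit images
#'
#' `read_image()` loads a PNG as a 0..255 numeric matrix (or H x W x 3
#' array), `write_image()` is its inverse. The image id defaults to the file
#' name without extension.
#'
#' @param path File path. Only PNG is supported.
#' @param image Numeric matrix or array with values in 0..255.
#' @return `read_image()`: the pixel grid; `write_image()`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image '%s' does not exist.", path))
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    abort("Only PNG images are supported by read_image().")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE] # drop alpha
    if (dim(px)[3] == 1L) px <- px[, , 1]
  }
  px <- round(px * 255)
  storage.mode(px) <- "integer"
  attr(px, "image_id") <- sub("\\.[^.]*$", "", basename(path))
  px
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  check_pixels(image)
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Convert an image to grayscale
#'
#' 3-channel images are collapsed with the BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded; single-channel input is
#' returned unchanged.
#'
#' @param image Numeric matrix or H x W x C array, C in \{1, 3\}.
#' @return A numeric H x W matrix in 0..255.
#' @export
to_grayscale <- function(image) {
  check_pixels(image)
  if (is.matrix(image)) {
    return(image)
  }
  d <- dim(image)
  if (d[3] == 1L) {
    out <- image[, , 1]
  } else {
    out <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] +
      0.114 * image[, , 3])
    storage.mode(out) <- "integer"
  }
  attr(out, "image_id") <- attr(image, "image_id")
  out
}

#' Describe an image enhancement
#'
#' Two enhancements feed the two counters: a percentile contrast stretch
#' (`"contrast"`, paired with the total-cell counter) and the Sobel gradient
#' magnitude (`"sobel"`, paired with the dead-cell counter, whose haloed dark
#' bodies have the strongest edges). `"identity"` leaves tiles untouched and
#' supports the unenhanced ablations.
#'
#' @param kind One of `"identity"`, `"contrast"`, `"sobel"`.
#' @param p_low,p_high Percentiles of the contrast stretch (defaults 1 and
#'   99); must satisfy `0 <= p_low < p_high <= 100`.
#' @return A list of class `enhancement_spec`.
#' @export
enhancement_spec <- function(kind = c("identity", "contrast", "sobel"),
                             p_low = 1, p_high = 99) {
  kind <- match.arg(kind)
  if (p_low < 0 || p_high > 100 || p_low >= p_high) {
    abort("Percentiles must satisfy 0 <= p_low < p_high <= 100.")
  }
  structure(list(kind = kind, p_low = p_low, p_high = p_high),
    class = "enhancement_spec"
  )
}

#' Enhancement 1: percentile contrast stretch
#'
#' Linearly rescales intensities so the `p_low` percentile maps to 0 and the
#' `p_high` percentile to 255, clamping outside values; the map is monotone
#' in pixel intensity. A constant image (equal percentiles) degenerates to an
#' all-zero image with a warning.
#'
#' @param image Grayscale numeric matrix, 0..255.
#' @param spec An [enhancement_spec()] with `kind = "contrast"`, or `NULL` to
#'   use `p_low`/`p_high`.
#' @param p_low,p_high Percentiles used when `spec` is `NULL`.
#' @return Enhanced 8-bit matrix of the same size.
#' @export
enhance_contrast <- function(image, spec = NULL, p_low = 1, p_high = 99) {
  check_pixels(image)
  if (!is.matrix(image)) abort("enhance_contrast() expects a grayscale matrix.")
  if (!is.null(spec)) {
    if (!identical(spec$kind, "contrast")) {
      abort("`spec$kind` must be \"contrast\" for enhance_contrast().")
    }
    p_low <- spec$p_low
    p_high <- spec$p_high
  }
  q <- quantile(image, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warn("Constant image: contrast stretch is undefined; returning all zeros.")
    out <- matrix(0, nrow(image), ncol(image))
  } else {
    out <- round(clamp(255 * (image - q[1]) / (q[2] - q[1]), 0, 255))
    storage.mode(out) <- "integer"
  }
  attr(out, "image_id") <- attr(image, "image_id")
  out
}

# Reflect (edge-mirroring) padding by one pixel on all sides.
pad_reflect1 <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' Sobel gradient magnitude (before rescale)
#'
#' Applies the 3x3 Sobel pair (Gx detecting horizontal gradients, Gy
#' vertical) with reflect padding at the border and returns
#' `sqrt(Gx^2 + Gy^2)` unrescaled — the quantity `enhance_sobel()` maps to
#' 0..255.
#'
#' @param image Grayscale numeric matrix.
#' @return Numeric matrix of gradient magnitudes (not 8-bit).
#' @export
sobel_magnitude <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("sobel_magnitude() expects a grayscale numeric matrix.")
  }
  h <- nrow(image)
  w <- ncol(image)
  p <- pad_reflect1(unclass(image))
  # index helper: p[r + dy, c + dx] over the interior
  sh <- function(dy, dx) p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Enhancement 2: Sobel edge enhancement
#'
#' Computes the Sobel gradient magnitude and rescales it linearly to 0..255.
#' On brightfield imagery this suppresses the flat background and the
#' low-contrast live cells while dead cells — dark cores ringed by a bright
#' detachment halo — appear as bright rings/dots.
#'
#' @param image Grayscale numeric matrix.
#' @param rescale If `TRUE` (default) min-max rescale the magnitude to
#'   0..255 8-bit; a constant-magnitude (e.g. constant input) image maps to
#'   all zeros.
#' @return Enhanced matrix, 8-bit when `rescale = TRUE`.
#' @export
enhance_sobel <- function(image, rescale = TRUE) {
  check_pixels(image)
  if (!is.matrix(image)) abort("enhance_sobel() expects a grayscale matrix.")
  mag <- sobel_magnitude(image)
  out <- if (!rescale) {
    mag
  } else {
    rng <- range(mag)
    if (rng[2] <= rng[1]) {
      matrix(0, nrow(mag), ncol(mag))
    } else {
      m8 <- round(255 * (mag - rng[1]) / (rng[2] - rng[1]))
      storage.mode(m8) <- "integer"
      m8
    }
  }
  attr(out, "image_id") <- attr(image, "image_id")
  out
}

#' Cut an image into non-overlapping 224x224 tiles
#'
#' The grid is anchored at the image origin; `floor(W/224) * floor(H/224)`
#' tiles are produced and right/bottom remainder pixels are discarded (a
#' 2048x1536 frame gives a 9x6 grid of 54 tiles). Tiles are ordered
#' row-major: grid row `j` varies slowest.
#'
#' @param image Grayscale numeric matrix (convert with [to_grayscale()]
#'   first).
#' @param tile_size Tile edge in pixels (default 224).
#' @return A tibble with columns `image_id`, `i` (0-based grid column), `j`
#'   (0-based grid row), `x0`, `y0` (pixel origin, multiples of
#'   `tile_size`) and `pixels` (list of `tile_size` x `tile_size` matrices).
#' @export
tile_image <- function(image, tile_size = 224L) {
  if (!is.matrix(image)) abort("tile_image() expects a grayscale matrix.")
  h <- nrow(image)
  w <- ncol(image)
  if (h < tile_size || w < tile_size) {
    abort(sprintf(
      "Image (%d x %d) is smaller than one %d x %d tile.",
      w, h, tile_size, tile_size
    ))
  }
  nx <- w %/% tile_size
  ny <- h %/% tile_size
  id <- image_id_of(image)
  grid <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  grid <- grid[order(grid$j, grid$i), ]
  tiles <- purrr::map2(grid$i, grid$j, function(i, j) {
    image[(j * tile_size + 1):((j + 1) * tile_size),
      (i * tile_size + 1):((i + 1) * tile_size),
      drop = FALSE
    ]
  })
  tibble::tibble(
    image_id = id,
    i = as.integer(grid$i), j = as.integer(grid$j),
    x0 = as.integer(grid$i * tile_size), y0 = as.integer(grid$j * tile_size),
    pixels = tiles
  )
}

#' Assign point annotations to tiles as count labels
#'
#' Each point lands in the unique tile containing it (half-open intervals:
#' tile column `i = floor(x / tile_size)`, row `j = floor(y / tile_size)`).
#' Points in the discarded right/bottom margin are dropped, counted, and
#' reported via a message and the `dropped` attribute. Per-tile labels are
#' the total and dead tallies the counters train on.
#'
#' @param tiles A tibble from [tile_image()] (one parent image).
#' @param set The image's [annotation_set()].
#' @param tile_size Tile edge used to build `tiles`.
#' @return `tiles` columns `image_id`, `i`, `j` plus `count_total` and
#'   `count_dead`, with attribute `dropped` (number of margin points).
#' @export
assign_labels <- function(tiles, set, tile_size = 224L) {
  stopifnot(inherits(set, "annotation_set"))
  if (length(unique(tiles$image_id)) > 1L) {
    abort("`tiles` must come from a single parent image.")
  }
  nx <- max(tiles$i) + 1L
  ny <- max(tiles$j) + 1L
  pi_ <- set$x %/% tile_size
  pj <- set$y %/% tile_size
  inside <- pi_ < nx & pj < ny & set$x >= 0 & set$y >= 0
  dropped <- sum(!inside)
  if (dropped > 0) {
    inform(sprintf(
      "%d point(s) fell in the discarded tiling margin and were dropped.",
      dropped
    ))
  }
  pts <- tibble::tibble(
    i = as.integer(pi_[inside]), j = as.integer(pj[inside]),
    dead = set$cls[inside] == "dead"
  )
  tallies <- pts |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(
      count_total = dplyr::n(),
      count_dead = sum(.data$dead),
      .groups = "drop"
    )
  out <- tiles |>
    dplyr::select("image_id", "i", "j") |>
    dplyr::left_join(tallies, by = c("i", "j")) |>
    dplyr::mutate(
      count_total = as.integer(tidyr::replace_na(.data$count_total, 0L)),
      count_dead = as.integer(tidyr::replace_na(.data$count_dead, 0L))
    )
  attr(out, "dropped") <- dropped
  out
}

#' Apply an enhancement to every tile
#'
#' Maps [enhance_contrast()] / [enhance_sobel()] over the `pixels` column of
#' a tile tibble. The Sobel rescale is per tile (each tile's magnitude is
#' stretched to 0..255 independently); for a per-image Sobel rescale, run
#' [enhance_sobel()] on the full frame before [tile_image()] instead. The
#' contrast stretch is usually applied per image for stable percentiles —
#' see [prepare_image()].
#'
#' @param tiles A tibble from [tile_image()].
#' @param spec An [enhancement_spec()].
#' @return `tiles` with the `pixels` column enhanced.
#' @export
enhance_tiles <- function(tiles, spec) {
  stopifnot(inherits(spec, "enhancement_spec"))
  f <- switch(spec$kind,
    identity = function(m) m,
    contrast = function(m) enhance_contrast(m, spec),
    sobel = function(m) enhance_sobel(m)
  )
  tiles$pixels <- purrr::map(tiles$pixels, f)
  tiles
}

#' Enhance and tile a full frame the way its counter expects
#'
#' The canonical preprocessing used throughout the pipeline: grayscale, then
#' for `"contrast"` the stretch is computed on the full frame (stable
#' percentiles) before tiling, while `"sobel"` is applied per tile (each
#' tile's magnitude rescaled independently). `"identity"` just tiles.
#'
#' @param image Image matrix or array.
#' @param spec An [enhancement_spec()].
#' @param tile_size Tile edge in pixels.
#' @return A tile tibble as from [tile_image()].
#' @export
prepare_image <- function(image, spec, tile_size = 224L) {
  g <- to_grayscale(image)
  if (spec$kind == "contrast") {
    tile_image(enhance_contrast(g, spec), tile_size)
  } else if (spec$kind == "sobel") {
    enhance_tiles(tile_image(g, tile_size), spec)
  } else {
    tile_image(g, tile_size)
  }
}
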