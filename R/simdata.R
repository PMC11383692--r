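# Synthetic brightfield scene generator.
#
# Emulates unstained phase-contrast imagery of an adherent culture:
#   * live cells  — elongated ellipses, slightly lighter than background,
#                   low contrast, no halo;
#   * dead cells  — circular bodies with a dark core and a bright halo
#                   annulus (detachment halo); radii are bimodal, spanning
#                   small shrunken apoptotic bodies and large swollen
#                   necrotic ones;
#   * artifacts   — faint cell-like blobs, statistically between live cells
#                   and background, that a total-cell counter can mistake
#                   for cells;
#   * background  — flat field plus additive Gaussian noise.
# Every rendered cell centre is returned as a point annotation, so the truth
# counts (and hence truth viability) are known by construction.

#' Configure a synthetic brightfield scene
#'
#' All geometry is in pixels on an 8-bit intensity scale. The defaults target
#' a 2048x1536 frame at roughly 10x-objective scale; none of them are
#' measured values — they are implementer-chosen to make live and dead
#' morphology separable in the way the enhancements exploit (see the package
#' vignette).
#'
#' @param width,height Frame size in pixels.
#' @param n_live,n_dead Number of live / dead cells to render.
#' @param live_shape List: `axis_range` (semi-major axis range, px) and
#'   `ecc_range` (ratio of minor to major axis; < 1 means elongated).
#' @param dead_shape List: `radius_small` (apoptotic mode, px),
#'   `radius_large` (necrotic mode, px), `p_small` (weight of the apoptotic
#'   mode).
#' @param dead_halo List: `width` (annulus width, px) and `offset` (intensity
#'   added above background).
#' @param intensity List: `bg_mean`, `bg_sd` (background level and Gaussian
#'   noise sd), `live_offset` (small positive: lighter, low contrast),
#'   `dead_offset` (negative: dark core), `artifact_offset`.
#' @param n_artifacts Number of distractor blobs.
#' @param artifact_radius Radius range of distractor blobs, px.
#' @param min_separation Minimum distance between any two object centres, px.
#' @param channels 1 (grayscale, default) or 3 (replicated, for parity with a
#'   colour camera).
#' @param seed RNG seed; identical seed and config give bit-identical scenes.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 2048, height = 1536,
                         n_live = 260, n_dead = 90,
                         live_shape = list(
                           axis_range = c(12, 24),
                           ecc_range = c(0.3, 0.6)
                         ),
                         dead_shape = list(
                           radius_small = c(3, 6),
                           radius_large = c(9, 16),
                           p_small = 0.4
                         ),
                         dead_halo = list(width = 3, offset = 30),
                         intensity = list(
                           bg_mean = 130, bg_sd = 8,
                           live_offset = 12, dead_offset = -55,
                           artifact_offset = 6
                         ),
                         n_artifacts = 15,
                         artifact_radius = c(3, 8),
                         min_separation = 26,
                         channels = 1,
                         seed = 1L) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_live = as.integer(n_live), n_dead = as.integer(n_dead),
    live_shape = live_shape, dead_shape = dead_shape,
    dead_halo = dead_halo, intensity = intensity,
    n_artifacts = as.integer(n_artifacts),
    artifact_radius = artifact_radius,
    min_separation = min_separation,
    channels = as.integer(channels),
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (cfg$width <= 0 || cfg$height <= 0) {
    abort("Scene dimensions must be positive.")
  }
  if (cfg$n_live < 0 || cfg$n_dead < 0 || cfg$n_artifacts < 0) {
    abort("Object counts must be non-negative.")
  }
  if (!cfg$channels %in% c(1L, 3L)) {
    abort("`channels` must be 1 or 3.")
  }
  lim <- min(cfg$width, cfg$height) / 4
  radii <- c(
    cfg$live_shape$axis_range, cfg$dead_shape$radius_small,
    cfg$dead_shape$radius_large, cfg$artifact_radius,
    max(cfg$dead_shape$radius_large) + cfg$dead_halo$width
  )
  if (any(radii >= lim)) {
    abort("All cell radii must be smaller than min(width, height) / 4.")
  }
  if (any(radii <= 0)) abort("Cell radii must be positive.")
  p <- cfg$dead_shape$p_small
  if (p < 0 || p > 1) abort("`p_small` must lie in [0, 1].")
  invisible(cfg)
}

# Rejection-sample integer centres (0-based) keeping min_separation between
# all accepted centres. `ext` gives each object's margin from the border.
place_centers <- function(n, ext, width, height, min_sep, max_attempts = 200L) {
  cx <- numeric(n)
  cy <- numeric(n)
  for (i in seq_len(n)) {
    lo_x <- ceiling(ext[i])
    hi_x <- width - 1 - ceiling(ext[i])
    lo_y <- ceiling(ext[i])
    hi_y <- height - 1 - ceiling(ext[i])
    if (hi_x < lo_x || hi_y < lo_y) {
      abort("Scene too small to place an object of the configured size.")
    }
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      px <- sample(lo_x:hi_x, 1L)
      py <- sample(lo_y:hi_y, 1L)
      if (i == 1L ||
        all((cx[seq_len(i - 1)] - px)^2 + (cy[seq_len(i - 1)] - py)^2 >=
          min_sep^2)) {
        cx[i] <- px
        cy[i] <- py
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "Could not place object %d of %d at min_separation = %s after %d attempts; lower the cell density.",
        i, n, format(min_sep), max_attempts
      ))
    }
  }
  list(x = cx, y = cy)
}

# Add `value` to the canvas over a mask defined by `inside(dx, dy)` evaluated
# on the object's bounding box. Centres are 0-based (x = column, y = row).
paint_object <- function(canvas, cx, cy, ext, inside, value) {
  h <- nrow(canvas)
  w <- ncol(canvas)
  r0 <- max(1L, cy + 1L - ceiling(ext))
  r1 <- min(h, cy + 1L + ceiling(ext))
  c0 <- max(1L, cx + 1L - ceiling(ext))
  c1 <- min(w, cx + 1L + ceiling(ext))
  rows <- r0:r1
  cols <- c0:c1
  dy <- matrix(rows - (cy + 1L), nrow = length(rows), ncol = length(cols))
  dx <- matrix(cols - (cx + 1L),
    nrow = length(rows), ncol = length(cols),
    byrow = TRUE
  )
  mask <- inside(dx, dy)
  sub <- canvas[rows, cols, drop = FALSE]
  sub[mask] <- sub[mask] + value
  canvas[rows, cols] <- sub
  canvas
}

#' Render one synthetic annotated scene
#'
#' Deterministically renders the scene described by a [scene_config()] and
#' returns the image together with the point annotations of every rendered
#' cell (artifacts are intentionally unannotated).
#'
#' @param config A [scene_config()].
#' @return A list with elements `image` (numeric matrix, or H x W x 3 array
#'   when `channels = 3`, values in 0..255, with an `image_id` attribute) and
#'   `annotations` (an [annotation_set()] with exactly `n_live` live and
#'   `n_dead` dead points at the rendered cell centres).
#' @examples
#' sc <- render_scene(scene_config(
#'   width = 256, height = 256, n_live = 8,
#'   n_dead = 3, n_artifacts = 2, seed = 7
#' ))
#' n_dead(sc$annotations)
#' @export
render_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    config <- do.call(scene_config, config)
  }
  validate_scene_config(config)
  withr::with_seed(config$seed, render_scene_impl(config))
}

render_scene_impl <- function(cfg) {
  inten <- cfg$intensity
  ls <- cfg$live_shape
  ds <- cfg$dead_shape

  # Sample morphology first (fixed order for determinism), then place.
  n_mode_small <- if (cfg$n_dead > 0) {
    sum(runif(cfg$n_dead) < ds$p_small)
  } else {
    0L
  }
  dead_r <- c(
    runif(n_mode_small, ds$radius_small[1], ds$radius_small[2]),
    runif(cfg$n_dead - n_mode_small, ds$radius_large[1], ds$radius_large[2])
  )
  if (cfg$n_dead > 0) dead_r <- sample(dead_r) # shuffle modes together
  live_a <- runif(cfg$n_live, ls$axis_range[1], ls$axis_range[2])
  live_b <- live_a * runif(cfg$n_live, ls$ecc_range[1], ls$ecc_range[2])
  live_theta <- runif(cfg$n_live, 0, pi)
  art_r <- runif(cfg$n_artifacts, cfg$artifact_radius[1], cfg$artifact_radius[2])

  ext <- c(dead_r + cfg$dead_halo$width, live_a, art_r)
  pos <- place_centers(
    length(ext), ext, cfg$width, cfg$height,
    cfg$min_separation
  )

  canvas <- matrix(inten$bg_mean, nrow = cfg$height, ncol = cfg$width)
  idx <- 0L
  for (i in seq_len(cfg$n_dead)) {
    idx <- idx + 1L
    r <- dead_r[i]
    hw <- cfg$dead_halo$width
    canvas <- paint_object(
      canvas, pos$x[idx], pos$y[idx], r + hw,
      function(dx, dy) dx^2 + dy^2 <= r^2, inten$dead_offset
    )
    canvas <- paint_object(
      canvas, pos$x[idx], pos$y[idx], r + hw,
      function(dx, dy) {
        d2 <- dx^2 + dy^2
        d2 > r^2 & d2 <= (r + hw)^2
      }, cfg$dead_halo$offset
    )
  }
  for (i in seq_len(cfg$n_live)) {
    idx <- idx + 1L
    a <- live_a[i]
    b <- live_b[i]
    th <- live_theta[i]
    canvas <- paint_object(
      canvas, pos$x[idx], pos$y[idx], a,
      function(dx, dy) {
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        (u / a)^2 + (v / b)^2 <= 1
      }, inten$live_offset
    )
  }
  for (i in seq_len(cfg$n_artifacts)) {
    idx <- idx + 1L
    r <- art_r[i]
    canvas <- paint_object(
      canvas, pos$x[idx], pos$y[idx], r,
      function(dx, dy) dx^2 + dy^2 <= r^2, inten$artifact_offset
    )
  }

  canvas <- canvas + rnorm(length(canvas), 0, inten$bg_sd)
  canvas <- round(clamp(canvas, 0, 255))
  storage.mode(canvas) <- "integer" # halves memory for large frames

  image_id <- sprintf("scene_seed%d", cfg$seed)
  if (cfg$channels == 3L) {
    canvas <- array(rep(canvas, 3L), dim = c(cfg$height, cfg$width, 3L))
  }
  attr(canvas, "image_id") <- image_id

  cls <- c(rep("dead", cfg$n_dead), rep("live", cfg$n_live))
  keep <- seq_len(cfg$n_dead + cfg$n_live)
  ann <- annotation_set(pos$x[keep], pos$y[keep], cls,
    image_id = image_id, width = cfg$width, height = cfg$height
  )
  list(image = canvas, annotations = ann)
}

#' Generate a dataset of synthetic annotated scenes
#'
#' Draws one truth viability per image uniformly in `viability_range` and one
#' total cell count uniformly in `density_range`, renders each scene with a
#' seed derived deterministically from `seed`, and returns everything as a
#' tibble — one row per image.
#'
#' @param n_images Number of images to generate (>= 1).
#' @param viability_range Length-2 numeric, percent, `0 <= low <= high <= 100`.
#' @param density_range Length-2 numeric: range of total cells per image.
#'   Defaults to ±30% around the base config's `n_live + n_dead`.
#' @param base_config A [scene_config()] providing geometry and intensities.
#' @param seed Master seed; per-image seeds derive from it.
#' @return A tibble with columns `image_id`, `image` (list), `annotations`
#'   (list), `n_live`, `n_dead`, `viability_truth_pct`, `seed`.
#' @export
make_dataset <- function(n_images, viability_range = c(13, 97),
                         density_range = NULL,
                         base_config = scene_config(), seed = 1L) {
  if (!is_count(n_images) || n_images < 1) {
    abort("`n_images` must be a positive integer.")
  }
  vr <- viability_range
  if (length(vr) != 2 || vr[1] > vr[2] || vr[1] < 0 || vr[2] > 100) {
    abort("`viability_range` must be [low, high] with 0 <= low <= high <= 100.")
  }
  if (!inherits(base_config, "scene_config")) {
    base_config <- do.call(scene_config, base_config)
  }
  if (is.null(density_range)) {
    n0 <- base_config$n_live + base_config$n_dead
    density_range <- c(round(0.7 * n0), round(1.3 * n0))
  }
  if (density_range[1] > density_range[2] || density_range[1] < 1) {
    abort("`density_range` must be [low, high] with low >= 1.")
  }

  seeds <- derive_seeds(seed, n_images + 1L)
  draws <- withr::with_seed(seeds[n_images + 1L], {
    list(
      v = runif(n_images, vr[1], vr[2]),
      n = round(runif(n_images, density_range[1], density_range[2]))
    )
  })

  rows <- purrr::map(seq_len(n_images), function(i) {
    n <- draws$n[i]
    n_live <- round(draws$v[i] / 100 * n)
    # keep the rounded truth inside the requested range
    n_live <- clamp(n_live, ceiling(vr[1] / 100 * n), floor(vr[2] / 100 * n))
    cfg <- base_config
    cfg$n_live <- as.integer(n_live)
    cfg$n_dead <- as.integer(n - n_live)
    cfg$seed <- seeds[i]
    sc <- render_scene(cfg)
    image_id <- sprintf("synthetic_%03d", i)
    attr(sc$image, "image_id") <- image_id
    attr(sc$annotations, "image_id") <- image_id
    tibble::tibble(
      image_id = image_id,
      image = list(sc$image),
      annotations = list(sc$annotations),
      n_live = cfg$n_live,
      n_dead = cfg$n_dead,
      viability_truth_pct = 100 * cfg$n_live / (cfg$n_live + cfg$n_dead),
      seed = seeds[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a synthetic dataset to disk as a labelled fixture
#'
#' Saves each image as an 8-bit PNG, each annotation set as a VIA JSON file,
#' and a manifest CSV tying them together.
#'
#' @param pairs A tibble from [make_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_fixture <- function(pairs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  manifest <- tibble::tibble(
    image_path = character(), json_path = character(),
    n_live = integer(), n_dead = integer(),
    viability_truth_pct = numeric(), seed = integer()
  )
  for (i in seq_len(nrow(pairs))) {
    id <- pairs$image_id[i]
    img_path <- file.path(out_dir, paste0(id, ".png"))
    json_path <- file.path(out_dir, paste0(id, ".json"))
    write_image(pairs$image[[i]], img_path)
    ann <- pairs$annotations[[i]]
    attr(ann, "image_id") <- paste0(id, ".png")
    write_via_json(ann, json_path)
    manifest <- dplyr::bind_rows(manifest, tibble::tibble(
      image_path = img_path, json_path = json_path,
      n_live = pairs$n_live[i], n_dead = pairs$n_dead[i],
      viability_truth_pct = pairs$viability_truth_pct[i],
      seed = pairs$seed[i]
    ))
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param manifest_path Path to a manifest CSV.
#' @return A tibble shaped like the output of [make_dataset()].
#' @export
read_fixture <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("Manifest '%s' does not exist.", manifest_path))
  }
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  rows <- purrr::map(seq_len(nrow(man)), function(i) {
    img <- read_image(resolve(man$image_path[i]))
    sets <- read_via_json(resolve(man$json_path[i]),
      width = ncol(img), height = nrow(img)
    )
    ann <- sets[[1]]
    id <- sub("\\.png$", "", basename(man$image_path[i]))
    attr(img, "image_id") <- id
    attr(ann, "image_id") <- id
    tibble::tibble(
      image_id = id, image = list(img), annotations = list(ann),
      n_live = n_live(ann), n_dead = n_dead(ann),
      viability_truth_pct = man$viability_truth_pct[i],
      seed = man$seed[i]
    )
  })
  dplyr::bind_rows(rows)
}
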