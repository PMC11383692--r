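# Point-annotation sets and VGG Image Annotator (VIA) JSON input/output.
#
# A point annotation marks the centre of one cell (the "small circle marker"
# an annotator drops on each cell) with a class: "live" or "dead". All
# ground-truth counts downstream derive from these sets.

#' Create a point-annotation set
#'
#' An annotation set is a tibble with one row per annotated cell and columns
#' `x`, `y` (0-based pixel coordinates; `x` is the column index, `y` the row
#' index) and `cls` (`"live"` or `"dead"`). The parent image identifier and,
#' when known, the image dimensions travel along as attributes so that
#' coordinates can be bounds-checked.
#'
#' @param x,y Integer pixel coordinates, 0-based. Fractional values are
#'   rounded half-up.
#' @param cls Character vector of classes, `"live"` or `"dead"`, recycled to
#'   the length of `x`.
#' @param image_id Identifier of the annotated image.
#' @param width,height Optional image dimensions in pixels; when supplied,
#'   every point must satisfy `0 <= x < width`, `0 <= y < height`.
#' @return A tibble of class `annotation_set` with columns `x`, `y`, `cls`.
#' @examples
#' ann <- annotation_set(c(10, 30), c(20, 40), c("dead", "live"), "img1")
#' n_live(ann)
#' @export
annotation_set <- function(x = integer(), y = integer(), cls = character(),
                           image_id = "image", width = NULL, height = NULL) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  if (length(x) > 0 && length(cls) == 0) {
    abort("`cls` must be supplied for non-empty annotation sets.")
  }
  cls <- as.character(rep_len(cls, length(x)))
  bad <- setdiff(unique(cls), c("live", "dead"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown annotation class(es): %s.", toString(bad)))
  }
  x <- round_half_up(x)
  y <- round_half_up(y)
  if (!is.null(width) && length(x) > 0 && any(x < 0 | x >= width)) {
    abort("Point x coordinates fall outside [0, width).")
  }
  if (!is.null(height) && length(y) > 0 && any(y < 0 | y >= height)) {
    abort("Point y coordinates fall outside [0, height).")
  }
  out <- tibble::tibble(x = as.integer(x), y = as.integer(y), cls = cls)
  structure(out,
    image_id = image_id, width = width, height = height,
    class = c("annotation_set", class(out))
  )
}

round_half_up <- function(v) floor(v + 0.5)

#' Annotation counts
#'
#' Tallies of an annotation set: live points, dead points, and their sum.
#' `n_total(set) == n_live(set) + n_dead(set)` always.
#'
#' @param set An [annotation_set()].
#' @return A single non-negative integer.
#' @export
n_live <- function(set) sum(set$cls == "live")

#' @rdname n_live
#' @export
n_dead <- function(set) sum(set$cls == "dead")

#' @rdname n_live
#' @export
n_total <- function(set) nrow(set)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> image '%s': %d live + %d dead = %d points\n",
    attr(x, "image_id"), n_live(x), n_dead(x), n_total(x)
  ))
  NextMethod()
}

new_annotation_like <- function(df, template) {
  annotation_set(df$x, df$y, df$cls,
    image_id = attr(template, "image_id"),
    width = attr(template, "width"), height = attr(template, "height")
  )
}

#' Read VIA point annotations from JSON
#'
#' Parses the VGG Image Annotator (VIA) JSON dialects: either the flat region
#' export keyed by `filename + size`, or a VIA2 project file with a top-level
#' `_via_img_metadata` entry. Only point-shaped regions
#' (`shape_attributes$name == "point"`, coordinates `cx`/`cy`) are accepted;
#' any other shape is an error naming the offending region. Fractional
#' coordinates are rounded half-up to integers.
#'
#' The live/dead class is read from the region attribute named by `cls_attr`
#' (default `"viability"`). Files produced from single-class annotation
#' sessions (all live, or all dead) often carry no class attribute at all; for
#' those, supply the class through `default_cls`.
#'
#' @param path Path to a VIA JSON file.
#' @param cls_attr Name of the region attribute holding the class.
#' @param default_cls Class (`"live"`/`"dead"`) assumed for regions without a
#'   class attribute. If `NULL`, such regions are an error.
#' @param width,height Optional image dimensions for bounds checking (bounds
#'   are only checked when the size is known).
#' @return A named list with one [annotation_set()] per image entry in the
#'   file, named by filename.
#' @export
read_via_json <- function(path, cls_attr = "viability", default_cls = NULL,
                          width = NULL, height = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Annotation file '%s' does not exist.", path))
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(sprintf("Failed to parse '%s' as VIA JSON: %s", path, conditionMessage(e)))
    }
  )
  if (!is.null(parsed[["_via_img_metadata"]])) {
    parsed <- parsed[["_via_img_metadata"]]
  }
  if (length(parsed) == 0) {
    return(list())
  }
  out <- list()
  for (key in names(parsed)) {
    entry <- parsed[[key]]
    fname <- entry$filename %||% key
    regions <- entry$regions %||% list()
    xs <- numeric(0)
    ys <- numeric(0)
    cl <- character(0)
    for (ridx in seq_along(regions)) {
      reg <- regions[[ridx]]
      sh <- reg$shape_attributes
      if (is.null(sh$name) || !identical(sh$name, "point")) {
        abort(sprintf(
          "Region %d of image '%s' has unsupported shape '%s' (only points are supported).",
          ridx, fname, sh$name %||% "<missing>"
        ))
      }
      if (is.null(sh$cx) || is.null(sh$cy)) {
        abort(sprintf("Region %d of image '%s' lacks cx/cy coordinates.", ridx, fname))
      }
      cls <- reg$region_attributes[[cls_attr]] %||% default_cls
      if (is.null(cls)) {
        abort(sprintf(
          "Region %d of image '%s' has no '%s' attribute and no `default_cls` was given.",
          ridx, fname, cls_attr
        ))
      }
      xs <- c(xs, sh$cx)
      ys <- c(ys, sh$cy)
      cl <- c(cl, cls)
    }
    set <- annotation_set(xs, ys, cl,
      image_id = fname, width = width, height = height
    )
    if (anyDuplicated(set[, c("x", "y")]) > 0) {
      warn(sprintf(
        "Image '%s': duplicated point coordinates found; keeping all (possibly the same cell labelled twice).",
        fname
      ))
    }
    out[[fname]] <- set
  }
  out
}

#' Write annotation sets as VIA JSON
#'
#' Writes the flat VIA region export (one entry per image, keyed
#' `filename + size`, with point-shaped regions). When `cls_filter` is given,
#' only points of that class are written — this reproduces the separate
#' live-only / dead-only annotation files of a single-class labelling
#' session.
#'
#' @param sets One [annotation_set()] or a list of them.
#' @param path Output path.
#' @param cls_filter Optional class (`"live"` or `"dead"`) to keep.
#' @param cls_attr Region attribute name used to store the class.
#' @return `path`, invisibly.
#' @export
write_via_json <- function(sets, path, cls_filter = NULL,
                           cls_attr = "viability") {
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  if (!is.null(cls_filter) && !cls_filter %in% c("live", "dead")) {
    abort("`cls_filter` must be \"live\", \"dead\" or NULL.")
  }
  doc <- list()
  for (set in sets) {
    fname <- attr(set, "image_id")
    pts <- set
    if (!is.null(cls_filter)) pts <- pts[pts$cls == cls_filter, ]
    regions <- purrr::pmap(
      list(pts$x, pts$y, pts$cls),
      function(x, y, cls) {
        list(
          shape_attributes = list(name = "point", cx = x, cy = y),
          region_attributes = setNames(list(cls), cls_attr)
        )
      }
    )
    doc[[paste0(fname, "-1")]] <- list(
      filename = fname,
      size = -1L,
      regions = regions,
      file_attributes = setNames(list(), character(0))
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Split an annotation set into the two training label sets
#'
#' The dead-cell counter trains on dead points only; the total-cell counter
#' trains on live and dead points combined. `split_labels()` produces both
#' from one mixed set.
#'
#' @param set An [annotation_set()].
#' @return A list with elements `dead` (dead points only) and `total` (all
#'   points); `n_total(total) == n_total(set)`.
#' @export
split_labels <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  dead <- new_annotation_like(set[set$cls == "dead", ], set)
  list(dead = dead, total = new_annotation_like(set, set))
}
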