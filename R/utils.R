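# Shared internal helpers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce to an 8-bit-valued numeric matrix/array and validate range.
check_pixels <- function(pixels, arg = "image") {
  if (!is.numeric(pixels)) {
    abort(sprintf("`%s` must be a numeric matrix or array.", arg))
  }
  nd <- length(dim(pixels))
  if (!(is.matrix(pixels) || (nd == 3L && dim(pixels)[3] %in% c(1L, 3L)))) {
    abort(sprintf(
      "`%s` must be an H x W matrix or an H x W x C array with C in {1, 3}.",
      arg
    ))
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    abort(sprintf("`%s` has intensities outside [0, 255].", arg))
  }
  invisible(pixels)
}

image_id_of <- function(pixels, default = "image") {
  attr(pixels, "image_id") %||% default
}

`image_id_of<-` <- function(pixels, value) {
  attr(pixels, "image_id") <- value
  pixels
}

# Deterministic child seeds below 2^31, derived from a master seed.
derive_seeds <- function(master, n) {
  withr::with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
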