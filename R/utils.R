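# Shared small helpers. All images in this package are numeric arrays with
# dim (height, width, channels) on the 8-bit scale 0..255; bounds are
# half-open integer intervals c(x0, y0, x1, y1) in the baseline (level 0)
# frame with origin at the top-left; sizes are c(width, height).

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "wsikit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "wsikit_validation_error") {
  if (!isTRUE(ok)) abort(msg, class)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# round half away from zero (R's round() is half-to-even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# round half to even on the 0..255 grid, used for 8-bit quantisation
quantize_8bit <- function(x) {
  pmin(pmax(round(x), 0), 255)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# recycle a scalar to length 2 (per-axis parameters such as mpp)
per_axis <- function(x, what = "value") {
  if (length(x) == 1L) x <- c(x, x)
  assert_that(length(x) == 2L, sprintf("%s must have length 1 or 2", what))
  as.numeric(x)
}

bounds_valid <- function(b) {
  is.numeric(b) && length(b) == 4L && all(is.finite(b)) &&
    b[1] < b[3] && b[2] < b[4]
}

assert_bounds <- function(b) {
  assert_that(bounds_valid(b),
              "bounds must be c(x0, y0, x1, y1) with x0 < x1 and y0 < y1")
}

bounds_extent <- function(b) c(b[3] - b[1], b[4] - b[2])

# ensure an image array has a channel dimension
as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  assert_that(is.array(img) && length(dim(img)) == 3L,
              "image must be a matrix or (h, w, c) array")
  img
}

image_dims <- function(img) {
  d <- dim(as_image_array(img))
  c(width = d[2], height = d[1], channels = d[3])
}
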