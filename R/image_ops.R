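# Separable resampling used by every read path. Downscales use exact area
# averaging (each output pixel is the mean of the source interval it covers),
# upscales use cubic convolution (Catmull-Rom), label rasters use nearest
# neighbour. All three are expressed as a per-axis weight matrix so that
# resize is two matrix products per channel.

cubic_kernel <- function(d, a = -0.5) {
  d <- abs(d)
  w <- numeric(length(d))
  i1 <- d <= 1
  i2 <- d > 1 & d < 2
  w[i1] <- (a + 2) * d[i1]^3 - (a + 3) * d[i1]^2 + 1
  w[i2] <- a * d[i2]^3 - 5 * a * d[i2]^2 + 8 * a * d[i2] - 4 * a
  w
}

# n_out x n_in row-stochastic weight matrix for one axis
resize_axis_weights <- function(n_in, n_out,
                                method = c("area", "bicubic", "bilinear")) {
  method <- match.arg(method)
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  if (method == "area") {
    lo <- (seq_len(n_out) - 1) * r
    hi <- seq_len(n_out) * r
    for (i in seq_len(n_out)) {
      j0 <- floor(lo[i]) + 1
      j1 <- ceiling(hi[i])
      j <- j0:min(j1, n_in)
      overlap <- pmin(hi[i], j) - pmax(lo[i], j - 1)
      overlap[overlap < 0] <- 0
      W[i, j] <- overlap
    }
  } else {
    support <- if (method == "bicubic") 2L else 1L
    kern <- if (method == "bicubic") cubic_kernel else function(d) pmax(0, 1 - abs(d))
    src <- (seq_len(n_out) - 0.5) * r - 0.5   # 0-based source position
    for (i in seq_len(n_out)) {
      base <- floor(src[i])
      taps <- (base - support + 1):(base + support)
      w <- kern(src[i] - taps)
      taps <- clamp(taps, 0, n_in - 1)        # clamp-to-edge
      for (k in seq_along(taps)) W[i, taps[k] + 1] <- W[i, taps[k] + 1] + w[k]
    }
  }
  sw <- rowSums(W)
  sw[sw == 0] <- 1
  W / sw
}

nearest_axis_index <- function(n_in, n_out) {
  r <- n_in / n_out
  idx <- floor((seq_len(n_out) - 0.5) * r) + 1
  clamp(idx, 1L, n_in)
}

#' Resize an image array
#'
#' Resamples an `(h, w, c)` array to a new width and height. `"area"`
#' performs exact area averaging (the natural choice for downscaling),
#' `"bicubic"` cubic convolution (for upscaling), `"bilinear"` linear
#' interpolation, and `"nearest"` nearest neighbour (used for label rasters
#' so that no new values are invented). `"auto"` picks area when shrinking
#' and bicubic when enlarging, per axis.
#'
#' @param img matrix or `(h, w, c)` array.
#' @param out_w,out_h output width and height in pixels.
#' @param method resampling method.
#' @return resized `(out_h, out_w, c)` array.
#' @export
resize_image <- function(img, out_w, out_h,
                         method = c("auto", "area", "bicubic", "bilinear",
                                    "nearest")) {
  method <- match.arg(method)
  img <- as_image_array(img)
  d <- dim(img)
  out_w <- as.integer(out_w); out_h <- as.integer(out_h)
  assert_that(out_w >= 1L && out_h >= 1L, "output size must be >= 1")
  if (out_w == d[2] && out_h == d[1]) return(img)
  if (method == "nearest") {
    iy <- nearest_axis_index(d[1], out_h)
    ix <- nearest_axis_index(d[2], out_w)
    return(img[iy, ix, , drop = FALSE])
  }
  pick <- function(n_in, n_out) {
    if (method != "auto") method else if (n_out <= n_in) "area" else "bicubic"
  }
  Wy <- resize_axis_weights(d[1], out_h, pick(d[1], out_h))
  Wx <- resize_axis_weights(d[2], out_w, pick(d[2], out_w))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- Wy %*% img[, , ch] %*% t(Wx)
  }
  out
}

# Pad an image by (top, bottom, left, right) pixels.
# mode "constant" fills with `value`; "reflect" mirrors without repeating the
# edge sample; "none" errors when any padding would be required.
pad_image <- function(img, top, bottom, left, right,
                      mode = c("constant", "reflect", "none"), value = 0) {
  mode <- match.arg(mode)
  img <- as_image_array(img)
  if (top == 0 && bottom == 0 && left == 0 && right == 0) return(img)
  if (mode == "none") {
    abort("read extends outside the slide and pad_mode is 'none'",
          "wsikit_validation_error")
  }
  d <- dim(img)
  reflect_idx <- function(i, n) {
    # reflect 0-based positions into [0, n-1] without edge repetition
    if (n == 1L) return(rep(1L, length(i)))
    p <- 2L * (n - 1L)
    m <- ((i %% p) + p) %% p
    ifelse(m < n, m, p - m) + 1L
  }
  iy <- (-top):(d[1] + bottom - 1L)
  ix <- (-left):(d[2] + right - 1L)
  if (mode == "reflect") {
    img[reflect_idx(iy, d[1]), reflect_idx(ix, d[2]), , drop = FALSE]
  } else {
    out <- array(value, c(length(iy), length(ix), d[3]))
    out[top + seq_len(d[1]), left + seq_len(d[2]), ] <- img
    out
  }
}

# Even-odd scanline rasterisation of polygons into a binary (h, w) matrix.
# `transform` maps geometry coordinates to pixel coordinates:
# px = (x - offset[1]) * scale[1], and a pixel (row, col) samples the point
# at (col - 0.5, row - 0.5) in the transformed frame.
rasterize_polygons <- function(polys, width, height,
                               scale = c(1, 1), offset = c(0, 0)) {
  scale <- per_axis(scale); offset <- per_axis(offset)
  mask <- matrix(FALSE, height, width)
  xs_sample <- (seq_len(width) - 0.5)
  for (poly in polys) {
    coords <- if (is.matrix(poly)) poly else poly$coords
    px <- (coords[, 1] - offset[1]) * scale[1]
    py <- (coords[, 2] - offset[2]) * scale[2]
    n <- length(px)
    if (n >= 2 && px[1] == px[n] && py[1] == py[n]) {
      px <- px[-n]; py <- py[-n]; n <- n - 1L
    }
    if (n < 3) next
    ymin <- max(1L, floor(min(py) + 0.5) + 1L)
    ymax <- min(height, ceiling(max(py) + 0.5))
    if (ymin > ymax) next
    jx <- c(seq_len(n)[-1], 1L)
    for (row in ymin:ymax) {
      yc <- row - 0.5
      crosses <- ((py <= yc) & (py[jx] > yc)) | ((py[jx] <= yc) & (py > yc))
      if (!any(crosses)) next
      i <- which(crosses)
      xint <- px[i] + (yc - py[i]) / (py[jx][i] - py[i]) * (px[jx][i] - px[i])
      xint <- sort(xint)
      inside <- rep(FALSE, width)
      for (k in seq(1, length(xint) - 1, by = 2)) {
        inside <- inside | (xs_sample >= xint[k] & xs_sample < xint[k + 1])
      }
      mask[row, ] <- mask[row, ] | inside
    }
  }
  mask
}
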