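# Grid and point patch enumeration. Patch size and stride are given in the
# OUTPUT (requested-resolution) frame and converted once to baseline pixels
# (round half away from zero) so a grid never drifts; coordinates are
# half-open baseline bounds.

#' Patch grid specification
#'
#' @param patch_size `(w, h)` in output pixels.
#' @param stride `(sx, sy)` in output pixels; defaults to `patch_size`
#'   (non-overlapping). A stride below the patch size yields overlapping
#'   patches.
#' @param res resolution patches are read at.
#' @param edge_policy `"discard_partial"` keeps only patches fully inside
#'   the slide; `"pad"` keeps every patch whose anchor is inside and pads.
#' @param pad_mode,pad_value padding for edge/point patches.
#' @param min_mask_ratio minimum tissue fraction for [filter_by_mask()].
#' @return a `patch_grid_spec`.
#' @export
patch_grid_spec <- function(patch_size, stride = NULL,
                            res = resolution(1, "baseline"),
                            edge_policy = c("discard_partial", "pad"),
                            pad_mode = "constant", pad_value = 0,
                            min_mask_ratio = 0.5) {
  edge_policy <- match.arg(edge_policy)
  patch_size <- per_axis(patch_size, "patch_size")
  stride <- if (is.null(stride)) patch_size else per_axis(stride, "stride")
  assert_that(all(patch_size >= 1) && all(stride >= 1),
              "patch_size and stride must be >= 1")
  assert_that(min_mask_ratio >= 0 && min_mask_ratio <= 1,
              "min_mask_ratio must be in [0, 1]")
  structure(list(patch_size = patch_size, stride = stride,
                 res = as_resolution(res), edge_policy = edge_policy,
                 pad_mode = pad_mode, pad_value = pad_value,
                 min_mask_ratio = min_mask_ratio),
            class = "patch_grid_spec")
}

# output-frame patch/stride -> baseline-frame integers
baseline_patch_geometry <- function(meta, spec) {
  scale <- relative_scale(meta, spec$res)
  list(patch = pmax(1, round_half_away(spec$patch_size / scale)),
       stride = pmax(1, round_half_away(spec$stride / scale)))
}

#' Enumerate grid patch coordinates
#'
#' Row-major enumeration of patch anchors at multiples of the stride,
#' converted to the baseline frame. With `edge_policy = "discard_partial"`
#' only patches fully inside the slide are kept (none when the patch exceeds
#' the slide); with `"pad"` every patch whose anchor lies inside is kept.
#'
#' @param meta a [wsi_meta()].
#' @param spec a [patch_grid_spec()].
#' @return data.frame with `key`, grid indices `i`, `j` (0-based, column /
#'   row), and half-open baseline bounds `x0, y0, x1, y1`.
#' @export
grid_coordinates <- function(meta, spec) {
  g <- baseline_patch_geometry(meta, spec)
  sd <- meta$slide_dimensions
  n_axis <- function(L, p, s, policy) {
    if (policy == "discard_partial") {
      if (L < p) 0L else floor((L - p) / s) + 1L
    } else {
      ceiling(L / s)
    }
  }
  nx <- n_axis(sd[1], g$patch[1], g$stride[1], spec$edge_policy)
  ny <- n_axis(sd[2], g$patch[2], g$stride[2], spec$edge_policy)
  if (nx == 0L || ny == 0L) {
    return(data.frame(key = character(), i = integer(), j = integer(),
                      x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  }
  i <- rep(seq_len(nx) - 1L, times = ny)   # column index, row-major order
  j <- rep(seq_len(ny) - 1L, each = nx)
  x0 <- i * g$stride[1]
  y0 <- j * g$stride[2]
  data.frame(key = sprintf("%04d_%04d", j, i), i = i, j = j,
             x0 = x0, y0 = y0, x1 = x0 + g$patch[1], y1 = y0 + g$patch[2])
}

#' Center patches on points
#'
#' One patch per point, centred on it in the baseline frame (anchor =
#' point - patch_extent / 2); edge patches rely on padding so the output
#' size stays homogeneous.
#'
#' @param points n x 2 matrix (or data.frame) of baseline `(x, y)`.
#' @param meta a [wsi_meta()].
#' @param spec a [patch_grid_spec()].
#' @return coordinate data.frame as [grid_coordinates()].
#' @export
points_to_coords <- function(points, meta, spec) {
  points <- as.matrix(points)
  assert_that(ncol(points) == 2 && all(is.finite(points)),
              "points must be a finite n x 2 matrix")
  g <- baseline_patch_geometry(meta, spec)
  n <- nrow(points)
  x0 <- round_half_away(points[, 1] - g$patch[1] / 2)
  y0 <- round_half_away(points[, 2] - g$patch[2] / 2)
  data.frame(key = sprintf("pt_%04d", seq_len(n) - 1L),
             i = seq_len(n) - 1L, j = rep(NA_integer_, n),
             x0 = x0, y0 = y0, x1 = x0 + g$patch[1], y1 = y0 + g$patch[2])
}

#' Filter patch coordinates by tissue mask
#'
#' Keeps patches whose footprint contains at least `min_mask_ratio` tissue,
#' measured on the mask raster at its native resolution. Any padded
#' (out-of-slide) part of a patch counts as non-tissue.
#'
#' @param coords coordinate data.frame.
#' @param mask_reader virtual mask reader from [make_mask()] (metadata
#'   synchronised with the slide).
#' @param min_mask_ratio minimum tissue fraction in `[0, 1]`.
#' @return filtered coordinate data.frame.
#' @export
filter_by_mask <- function(coords, mask_reader, min_mask_ratio = 0.5) {
  if (nrow(coords) == 0) return(coords)
  mask <- mask_reader$levels[[1L]]
  d <- dim(mask)
  sd <- mask_reader$meta$slide_dimensions
  fx <- d[2] / sd[1]
  fy <- d[1] / sd[2]
  frac <- vapply(seq_len(nrow(coords)), function(k) {
    b <- as.numeric(coords[k, c("x0", "y0", "x1", "y1")])
    mx0 <- b[1] * fx; mx1 <- b[3] * fx
    my0 <- b[2] * fy; my1 <- b[4] * fy
    ix <- floor(mx0):(ceiling(mx1) - 1)
    iy <- floor(my0):(ceiling(my1) - 1)
    # per-cell coverage weights handle patches smaller than a mask pixel
    wx <- pmin(mx1, ix + 1) - pmax(mx0, ix)
    wy <- pmin(my1, iy + 1) - pmax(my0, iy)
    inx <- ix >= 0 & ix < d[2]
    iny <- iy >= 0 & iy < d[1]
    w <- outer(wy, wx)
    vals <- matrix(0, length(iy), length(ix))
    if (any(inx) && any(iny)) {
      vals[iny, inx] <- mask[iy[iny] + 1, ix[inx] + 1, 1]
    }
    sum(w * vals) / sum(w)
  }, numeric(1))
  coords[frac >= min_mask_ratio, , drop = FALSE]
}

#' Lazily iterate patches
#'
#' Returns an iterator function producing `list(coord, image)` on each call
#' and `NULL` when exhausted. Patches are read on demand through
#' [read_rect()] (no patch is materialised before it is requested) in
#' coordinate order; every image is exactly `patch_size`.
#'
#' @param reader a `wsi_reader`.
#' @param coords coordinate data.frame.
#' @param spec the [patch_grid_spec()] the coordinates were built with.
#' @return function: call repeatedly to obtain patches.
#' @export
iter_patches <- function(reader, coords, spec) {
  k <- 0L
  function() {
    k <<- k + 1L
    if (k > nrow(coords)) return(NULL)
    coord <- coords[k, , drop = FALSE]
    img <- tryCatch(
      read_rect(reader, c(coord$x0, coord$y0), spec$patch_size,
                res = spec$res, pad_mode = spec$pad_mode,
                pad_value = spec$pad_value),
      error = function(e) {
        abort(sprintf("patch read failed at %s (%g, %g): %s", coord$key,
                      coord$x0, coord$y0, conditionMessage(e)),
              "wsikit_read_error")
      })
    list(coord = coord, image = img)
  }
}

collect_patches <- function(reader, coords, spec) {
  it <- iter_patches(reader, coords, spec)
  out <- vector("list", nrow(coords))
  for (k in seq_len(nrow(coords))) out[[k]] <- it()$image
  out
}
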