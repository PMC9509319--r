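# Unified random-access reading. Two backend families:
#   * pyramidal: stored levels; reads pick the best stored level (plan_read)
#     and resample the residual factor (area down / bicubic up).
#   * flat: a single raster (PNG/JPEG/array, or a virtual pyramid wrapping a
#     derived raster with a donor slide's metadata); reads sample the raster
#     directly -- bilinear for intensity data, nearest neighbour for labels.
# All public reads take baseline-frame coordinates and a resolution request.

new_reader <- function(backend, levels, meta, interpretation = "intensity",
                       virtual = FALSE) {
  structure(list(backend = backend, levels = levels, meta = meta,
                 interpretation = interpretation, virtual = virtual),
            class = "wsi_reader")
}

#' @export
print.wsi_reader <- function(x, ...) {
  cat(sprintf("<wsi_reader backend=%s%s>\n", x$backend,
              if (x$virtual) " (virtual)" else ""))
  print(x$meta)
  invisible(x)
}

#' Open a reader over a slide, flat image or array
#'
#' Returns a unified reader for pyramidal/flat TIFFs, PNG or JPEG visual
#' fields, or in-memory arrays. Metadata is populated into a [wsi_meta()];
#' `mpp` and `objective_power` overrides take precedence over anything found
#' in the file (X/YResolution TIFF tags are parsed to mpp when present).
#'
#' @param source file path, or matrix/array of pixel data (0..255 or 0..1).
#' @param mpp override microns-per-pixel.
#' @param objective_power override nominal magnification.
#' @return a `wsi_reader`.
#' @export
open_reader <- function(source, mpp = NULL, objective_power = NULL) {
  if (is.character(source)) {
    assert_that(length(source) == 1 && file.exists(source),
                sprintf("no such file: %s", source[1]), "wsikit_format_error")
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("tif", "tiff")) {
      return(open_tiff_reader(source, mpp, objective_power))
    }
    if (ext %in% c("png", "jpg", "jpeg")) {
      img <- tryCatch(
        if (ext == "png") png::readPNG(source) else jpeg::readJPEG(source),
        error = function(e) abort(sprintf("cannot read %s: %s", source,
                                          conditionMessage(e)),
                                  "wsikit_format_error"))
      return(open_array_reader(img * 255, mpp, objective_power,
                               vendor = ext))
    }
    abort(sprintf("unsupported file extension: %s", ext),
          "wsikit_format_error")
  }
  if (is.numeric(source) && (is.matrix(source) || is.array(source))) {
    return(open_array_reader(source, mpp, objective_power, vendor = "array"))
  }
  abort("source must be a file path or a numeric matrix/array",
        "wsikit_format_error")
}

open_tiff_reader <- function(path, mpp, objective_power) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      abort(sprintf("cannot read TIFF %s: %s", path,
                                    conditionMessage(e)),
                            "wsikit_format_error"))
  if (!is.list(pages)) pages <- list(pages)
  levels <- lapply(pages, function(p) as_image_array(p) * 255)
  dims <- lapply(levels, function(l) c(dim(l)[2], dim(l)[1]))
  if (is.null(mpp)) {
    xr <- attr(pages[[1]], "x.resolution")
    yr <- attr(pages[[1]], "y.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xr) && !is.null(unit) && unit %in% c("cm", "inch")) {
      per_um <- if (unit == "cm") 1e4 else 25400
      mpp <- c(per_um / xr, per_um / if (is.null(yr)) xr else yr)
    }
  }
  meta <- wsi_meta(slide_dimensions = dims[[1]], level_dimensions = dims,
                   mpp = mpp, objective_power = objective_power,
                   vendor = "tiff",
                   raw = lapply(pages, attributes))
  new_reader("tiff", levels, meta)
}

open_array_reader <- function(img, mpp, objective_power, vendor = "array") {
  img <- as_image_array(img)
  if (max(img) <= 1 && min(img) >= 0) img <- img * 255
  d <- dim(img)
  meta <- wsi_meta(slide_dimensions = c(d[2], d[1]),
                   level_dimensions = list(c(d[2], d[1])),
                   mpp = mpp, objective_power = objective_power,
                   vendor = vendor)
  new_reader(vendor, list(img), meta)
}

#' Wrap a derived raster as a virtual pyramid
#'
#' Wraps a flat raster (tissue mask, prediction map, ...) so that it answers
#' reads with a donor slide's metadata and coordinate frame: reads on the
#' wrapped raster and the donor slide with identical arguments return
#' aligned outputs. `interpretation = "label"` restricts sampling to nearest
#' neighbour so only original label values appear.
#'
#' @param image matrix or array; dimensions must be proportional to the
#'   donor slide dimensions within 1% per axis.
#' @param donor_meta the donor slide's [wsi_meta()].
#' @param interpretation `"intensity"` or `"label"`.
#' @return a virtual `wsi_reader`.
#' @export
as_virtual <- function(image, donor_meta,
                       interpretation = c("intensity", "label")) {
  interpretation <- match.arg(interpretation)
  assert_that(inherits(donor_meta, "wsi_meta"), "donor_meta must be wsi_meta")
  img <- as_image_array(image)
  d <- dim(img)
  sd <- donor_meta$slide_dimensions
  fx <- d[2] / sd[1]
  fy <- d[1] / sd[2]
  # proportional within 1% per axis; small rasters get a +-1 px allowance
  # since their dimensions are rounded
  ok <- abs(fx / fy - 1) <= 0.01 ||
    (abs(sd[1] * fy - d[2]) <= 1 && abs(sd[2] * fx - d[1]) <= 1)
  assert_that(ok, "image aspect ratio does not match donor slide (>1% off)")
  new_reader("virtual", list(img), donor_meta,
             interpretation = interpretation, virtual = TRUE)
}

# ---------------------------------------------------------------------------

# Core region read shared by read_rect / read_bounds: continuous baseline
# bounds in, exact (out_w, out_h) image out.
read_region_core <- function(reader, bounds, out_size, scale,
                             pad_mode = "constant", pad_value = 0) {
  meta <- reader$meta
  out_w <- as.integer(out_size[1]); out_h <- as.integer(out_size[2])
  if (reader$virtual || length(reader$levels) == 1L && reader$backend != "tiff") {
    return(sample_flat(reader, bounds, out_w, out_h, pad_mode, pad_value))
  }
  plan <- plan_read(meta, bounds, resolution(min(scale), "baseline"))
  lvl <- reader$levels[[plan$source_level + 1L]]
  reg <- plan$level_region
  ld <- dim(lvl)
  # clamp to the level, then pad back to the requested region
  cx0 <- clamp(reg[1], 0, ld[2]); cx1 <- clamp(reg[3], 0, ld[2])
  cy0 <- clamp(reg[2], 0, ld[1]); cy1 <- clamp(reg[4], 0, ld[1])
  if (cx1 > cx0 && cy1 > cy0) {
    block <- lvl[(cy0 + 1):cy1, (cx0 + 1):cx1, , drop = FALSE]
  } else {
    block <- array(pad_value, c(1, 1, ld[3]))
    cx0 <- reg[1]; cx1 <- reg[1] + 1; cy0 <- reg[2]; cy1 <- reg[2] + 1
  }
  block <- pad_image(block,
                     top = cy0 - reg[2], bottom = reg[4] - cy1,
                     left = cx0 - reg[1], right = reg[3] - cx1,
                     mode = pad_mode, value = pad_value)
  method <- if (reader$interpretation == "label") "nearest" else "auto"
  resize_image(block, out_w, out_h, method = method)
}

# Direct sampling for flat/virtual rasters: map output pixel centres to the
# raster frame; bilinear for intensity, nearest for labels; constant or
# reflect padding outside the raster.
sample_flat <- function(reader, bounds, out_w, out_h, pad_mode, pad_value) {
  img <- reader$levels[[1L]]
  d <- dim(img)
  meta <- reader$meta
  fx <- d[2] / meta$slide_dimensions[1]
  fy <- d[1] / meta$slide_dimensions[2]
  ext <- bounds_extent(bounds)
  # 0-based continuous source positions of output pixel centres
  px <- (bounds[1] + (seq_len(out_w) - 0.5) * ext[1] / out_w) * fx
  py <- (bounds[2] + (seq_len(out_h) - 0.5) * ext[2] / out_h) * fy
  nearest <- reader$interpretation == "label" ||
    (out_w <= 1 && out_h <= 1)
  reflect <- function(i, n) {
    p <- 2L * n
    m <- ((i %% p) + p) %% p
    ifelse(m < n, m, p - 1L - m)
  }
  fetch_idx <- function(i, n) {
    # 0-based index -> 1-based clamped, with out-of-range marker
    if (pad_mode == "reflect") {
      reflect(i, n) + 1L
    } else {
      clamp(i, 0L, n - 1L) + 1L
    }
  }
  if (nearest) {
    ix <- floor(px); iy <- floor(py)
    ox <- ix < 0 | ix >= d[2]; oy <- iy < 0 | iy >= d[1]
    out <- img[fetch_idx(iy, d[1]), fetch_idx(ix, d[2]), , drop = FALSE]
    if (pad_mode == "constant" && (any(ox) || any(oy))) {
      out[oy, , ] <- pad_value
      out[, ox, ] <- pad_value
    }
    if (pad_mode == "none" && (any(ox) || any(oy))) {
      abort("read extends outside the raster and pad_mode is 'none'",
            "wsikit_validation_error")
    }
    return(out)
  }
  tx <- px - 0.5; ty <- py - 0.5
  jx <- floor(tx); jy <- floor(ty)
  wx <- tx - jx;  wy <- ty - jy
  ix0 <- fetch_idx(jx, d[2]);      ix1 <- fetch_idx(jx + 1, d[2])
  iy0 <- fetch_idx(jy, d[1]);      iy1 <- fetch_idx(jy + 1, d[1])
  out <- array(0, c(out_h, out_w, d[3]))
  Wy0 <- matrix(1 - wy, out_h, out_w); Wx0 <- matrix(1 - wx, out_h, out_w,
                                                     byrow = TRUE)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    out[, , ch] <-
      plane[iy0, ix0] * Wy0 * Wx0 +
      plane[iy0, ix1] * Wy0 * (1 - Wx0) +
      plane[iy1, ix0] * (1 - Wy0) * Wx0 +
      plane[iy1, ix1] * (1 - Wy0) * (1 - Wx0)
  }
  oob_x <- px < 0 | px > d[2]
  oob_y <- py < 0 | py > d[1]
  if (pad_mode == "constant" && (any(oob_x) || any(oob_y))) {
    out[oob_y, , ] <- pad_value
    out[, oob_x, ] <- pad_value
  }
  if (pad_mode == "none" && (any(oob_x) || any(oob_y))) {
    abort("read extends outside the raster and pad_mode is 'none'",
          "wsikit_validation_error")
  }
  out
}

#' Read a region with a fixed output size
#'
#' Reads a region anchored at `location` (baseline pixels, top-left) whose
#' output is exactly `size = (w, h)` pixels at the requested resolution: the
#' field of view is `size / scale` baseline pixels, so it widens as the
#' requested resolution coarsens. Out-of-slide area is filled according to
#' `pad_mode`.
#'
#' @param reader a `wsi_reader`.
#' @param location `(x, y)` anchor in baseline pixels.
#' @param size `(w, h)` output size in pixels.
#' @param res a [resolution()] (bare numbers are baseline scale fractions).
#' @param pad_mode `"constant"`, `"reflect"` or `"none"` (error on padding).
#' @param pad_value fill value for constant padding.
#' @return `(h, w, c)` array, exactly the requested size.
#' @export
read_rect <- function(reader, location, size, res = resolution(1, "baseline"),
                      pad_mode = c("constant", "reflect", "none"),
                      pad_value = 0) {
  pad_mode <- match.arg(pad_mode)
  assert_that(length(size) == 2 && all(size >= 1),
              "size must be (w, h) >= 1")
  assert_that(length(location) == 2 && all(is.finite(location)),
              "location must be (x, y)")
  res <- as_resolution(res)
  scale <- relative_scale(reader$meta, res)
  ext <- size / scale
  bounds <- c(location[1], location[2], location[1] + ext[1],
              location[2] + ext[2])
  read_region_core(reader, bounds, size, scale, pad_mode, pad_value)
}

#' Read a region with a fixed field of view
#'
#' Reads the region `bounds` (baseline pixels, half-open) at the requested
#' resolution: the depicted tissue is invariant to `res` while the output
#' dimensions scale as `round(extent * scale)`.
#'
#' @inheritParams read_rect
#' @param bounds `c(x0, y0, x1, y1)` in baseline pixels.
#' @export
read_bounds <- function(reader, bounds, res = resolution(1, "baseline"),
                        pad_mode = c("constant", "reflect", "none"),
                        pad_value = 0) {
  pad_mode <- match.arg(pad_mode)
  assert_bounds(bounds)
  res <- as_resolution(res)
  scale <- relative_scale(reader$meta, res)
  out <- pmax(1, round(bounds_extent(bounds) * scale))
  read_region_core(reader, bounds, out, scale, pad_mode, pad_value)
}

#' Whole-slide thumbnail
#'
#' [read_bounds()] over the full slide extent.
#' @inheritParams read_rect
#' @export
slide_thumbnail <- function(reader, res = resolution(1 / 32, "baseline")) {
  sd <- reader$meta$slide_dimensions
  read_bounds(reader, c(0, 0, sd[1], sd[2]), res)
}
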