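# Unified slide metadata and the resolution-request currency. Every read in
# the package is phrased as (region in baseline pixels, resolution request);
# relative_scale() turns a request into output-pixels-per-baseline-pixel.

#' Unified whole-slide metadata
#'
#' A single metadata object populated by every reader backend: baseline
#' dimensions, pyramid level dimensions and downsamples, physical resolution
#' (microns-per-pixel) and nominal objective power when known, and the raw
#' backend metadata for reference.
#'
#' @param slide_dimensions baseline `(width, height)` in pixels.
#' @param level_dimensions list of `(width, height)` per level, baseline
#'   first.
#' @param level_downsamples numeric downsample per level; computed from the
#'   dimensions when omitted.
#' @param mpp microns-per-pixel, length 1 or 2, or `NULL` when unknown.
#' @param objective_power nominal magnification or `NULL`.
#' @param vendor backend/vendor tag.
#' @param raw opaque original metadata.
#' @return a `wsi_meta` object.
#' @export
wsi_meta <- function(slide_dimensions, level_dimensions,
                     level_downsamples = NULL, mpp = NULL,
                     objective_power = NULL, vendor = NULL, raw = NULL) {
  slide_dimensions <- as.numeric(slide_dimensions)
  assert_that(length(slide_dimensions) == 2 && all(slide_dimensions >= 1),
              "slide_dimensions must be (width, height) >= 1")
  assert_that(is.list(level_dimensions) && length(level_dimensions) >= 1,
              "level_dimensions must be a non-empty list")
  level_dimensions <- lapply(level_dimensions, as.numeric)
  if (is.null(level_downsamples)) {
    level_downsamples <- vapply(level_dimensions, function(d) {
      mean(slide_dimensions / d)
    }, numeric(1))
  }
  assert_that(abs(level_downsamples[1] - 1) < 1e-9,
              "level_downsamples[1] must be 1.0")
  assert_that(all(diff(level_downsamples) > 0),
              "level_downsamples must be strictly increasing")
  for (l in seq_along(level_dimensions)) {
    approx <- slide_dimensions / level_downsamples[l]
    assert_that(all(abs(level_dimensions[[l]] - approx) <= 1),
                sprintf("level %d dimensions inconsistent with downsample", l - 1))
  }
  if (!is.null(mpp)) {
    mpp <- per_axis(mpp, "mpp")
    assert_that(all(mpp > 0), "mpp must be positive")
  }
  if (!is.null(objective_power)) {
    assert_that(is_scalar_number(objective_power) && objective_power > 0,
                "objective_power must be positive")
  }
  structure(list(
    slide_dimensions = slide_dimensions,
    level_count = length(level_dimensions),
    level_dimensions = level_dimensions,
    level_downsamples = as.numeric(level_downsamples),
    mpp = mpp, objective_power = objective_power,
    vendor = vendor, raw = raw
  ), class = "wsi_meta")
}

#' @export
print.wsi_meta <- function(x, ...) {
  cat(sprintf("<wsi_meta %d x %d px, %d level(s)>\n",
              x$slide_dimensions[1], x$slide_dimensions[2], x$level_count))
  cat("  downsamples:", paste(signif(x$level_downsamples, 4), collapse = ", "),
      "\n")
  if (!is.null(x$mpp)) cat("  mpp:", paste(x$mpp, collapse = ", "), "\n")
  if (!is.null(x$objective_power)) cat("  power:", x$objective_power, "\n")
  invisible(x)
}

RES_UNITS <- c("mpp", "power", "level", "baseline")

#' Resolution request
#'
#' The currency of every read: a value plus its units. `"mpp"` requests a
#' physical sampling resolution in microns-per-pixel, `"power"` an apparent
#' magnification, `"level"` a stored pyramid level by index (0 = baseline),
#' and `"baseline"` a plain scale fraction of level 0.
#'
#' @param value resolution value (or level index for `units = "level"`).
#' @param units one of `"mpp"`, `"power"`, `"level"`, `"baseline"`.
#' @export
resolution <- function(value, units = c("mpp", "power", "level", "baseline")) {
  units <- match.arg(units)
  if (units == "mpp") {
    value <- per_axis(value, "mpp")
    assert_that(all(value > 0), "mpp must be positive")
  } else {
    assert_that(is_scalar_number(value), "resolution value must be a scalar")
    if (units == "level") {
      assert_that(value >= 0 && value == floor(value),
                  "level must be a nonnegative integer")
    } else {
      assert_that(value > 0, "resolution value must be positive")
    }
  }
  structure(list(value = value, units = units), class = "wsi_resolution")
}

as_resolution <- function(res) {
  if (inherits(res, "wsi_resolution")) return(res)
  assert_that(is.numeric(res), "resolution must be a wsi_resolution or numeric")
  resolution(res, "baseline")
}

#' Output scale of a resolution request
#'
#' Converts a resolution request into output pixels per baseline pixel for
#' each axis: `mpp` gives `meta$mpp / value`, `power` gives
#' `value / meta$objective_power`, `level` gives
#' `1 / level_downsamples[level]`, and `baseline` is the value itself.
#'
#' @param meta a [wsi_meta()].
#' @param res a [resolution()].
#' @return numeric length-2 `(sx, sy)`.
#' @export
relative_scale <- function(meta, res) {
  res <- as_resolution(res)
  switch(res$units,
    mpp = {
      if (is.null(meta$mpp)) {
        abort("slide has no mpp metadata; cannot honour an mpp request",
              "wsikit_unit_error")
      }
      meta$mpp / per_axis(res$value)
    },
    power = {
      if (is.null(meta$objective_power)) {
        abort("slide has no objective power; cannot honour a power request",
              "wsikit_unit_error")
      }
      rep(res$value / meta$objective_power, 2)
    },
    level = {
      assert_that(res$value < meta$level_count,
                  sprintf("level %d out of range (%d levels)",
                          res$value, meta$level_count))
      rep(1 / meta$level_downsamples[res$value + 1], 2)
    },
    baseline = rep(res$value, 2)
  )
}

#' Plan a pyramidal read
#'
#' Chooses the source level for a read: the stored level with the largest
#' downsample `d` still satisfying `d <= 1/scale` (so the read never
#' upsamples a lower-resolution level), falling back to the baseline with an
#' upscale warning when the request exceeds baseline resolution. The region
#' to read on that level and the residual post-scale are returned.
#'
#' @param meta a [wsi_meta()].
#' @param baseline_bounds `c(x0, y0, x1, y1)` in baseline pixels; may extend
#'   outside the slide.
#' @param res a [resolution()].
#' @return a `read_plan` with `source_level` (0-based), `level_region`,
#'   `post_scale` and `pad_spec` (left, top, right, bottom, output pixels).
#' @export
plan_read <- function(meta, baseline_bounds, res) {
  assert_bounds(baseline_bounds)
  scale <- relative_scale(meta, res)
  s <- min(scale)
  ok <- which(meta$level_downsamples <= 1 / s + 1e-9)
  if (length(ok) == 0) ok <- 1L
  source_level <- max(ok) - 1L
  if (s > 1 + 1e-9) {
    warning("requested resolution exceeds baseline; upscaling",
            call. = FALSE)
  }
  d <- meta$level_downsamples[source_level + 1L]
  region <- c(floor(baseline_bounds[1:2] / d), ceiling(baseline_bounds[3:4] / d))
  sw <- bounds_extent(baseline_bounds) * scale
  pad <- c(
    left   = max(0, -baseline_bounds[1]) * scale[1],
    top    = max(0, -baseline_bounds[2]) * scale[2],
    right  = max(0, baseline_bounds[3] - meta$slide_dimensions[1]) * scale[1],
    bottom = max(0, baseline_bounds[4] - meta$slide_dimensions[2]) * scale[2]
  )
  structure(list(source_level = source_level, level_region = region,
                 post_scale = scale * d, pad_spec = pad,
                 scale = scale, out_extent = sw),
            class = "read_plan")
}
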