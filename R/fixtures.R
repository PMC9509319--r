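# Synthetic-fixture module: pyramidal slides with known metadata and tissue
# layout, Beer-Lambert two-stain images with exact concentration/stain-matrix
# ground truth, and random annotation collections. Everything downstream is
# tested against these generators, so their outputs carry sidecar records of
# exactly what was synthesized.

#' Specification of a synthetic pyramidal slide
#'
#' Describes the slide the fixture generator should synthesize: baseline
#' dimensions, number of pyramid levels (each level halves the previous one,
#' dimensions `ceiling(baseline / 2^level)`), physical resolution in
#' microns-per-pixel, nominal objective power, elliptical tissue blobs and a
#' near-white noisy background.
#'
#' @param width_px,height_px baseline dimensions in pixels.
#' @param n_levels number of pyramid levels (>= 1).
#' @param mpp microns-per-pixel, length 1 or 2 `(x, y)`.
#' @param objective_power nominal scan magnification (e.g. 40).
#' @param tissue_blobs list of `list(center = c(x, y), radii = c(rx, ry),
#'   rotation = radians)`; `NULL` places two default blobs.
#' @param background_gray background intensity, 0..255.
#' @param seed integer seed controlling all randomness in the render.
#' @return a `slide_spec` object.
#' @export
slide_spec <- function(width_px, height_px, n_levels = 3L, mpp = 0.5,
                       objective_power = 40, tissue_blobs = NULL,
                       background_gray = 245L, seed = 42L) {
  assert_that(is_scalar_number(width_px) && width_px >= 1 &&
                is_scalar_number(height_px) && height_px >= 1,
              "slide dimensions must be >= 1")
  assert_that(is_scalar_number(n_levels) && n_levels >= 1,
              "n_levels must be >= 1")
  mpp <- per_axis(mpp, "mpp")
  assert_that(all(mpp > 0), "mpp must be positive")
  assert_that(is_scalar_number(objective_power) && objective_power > 0,
              "objective_power must be positive")
  assert_that(is_scalar_number(background_gray) && background_gray >= 0 &&
                background_gray <= 255, "background_gray must be in 0..255")
  if (is.null(tissue_blobs)) {
    w <- width_px; h <- height_px
    tissue_blobs <- list(
      list(center = c(0.32 * w, 0.38 * h), radii = c(0.20 * w, 0.22 * h),
           rotation = 0.4),
      list(center = c(0.70 * w, 0.66 * h), radii = c(0.17 * w, 0.20 * h),
           rotation = -0.7)
    )
  }
  for (b in tissue_blobs) {
    assert_that(length(b$center) == 2 && length(b$radii) == 2 &&
                  all(b$radii > 0), "invalid tissue blob")
  }
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    n_levels = as.integer(n_levels), mpp = mpp,
    objective_power = as.numeric(objective_power),
    tissue_blobs = tissue_blobs,
    background_gray = as.numeric(background_gray),
    seed = as.integer(seed)
  ), class = "slide_spec")
}

spec_level_dims <- function(spec) {
  lapply(seq_len(spec$n_levels) - 1L, function(l) {
    c(ceiling(spec$width_px / 2^l), ceiling(spec$height_px / 2^l))
  })
}

# Default Hematoxylin/Eosin stain vectors in OD space (unit rows, H first).
#' @export
#' @rdname stain_ground_truth
default_stain_matrix <- function() {
  m <- rbind(c(0.65, 0.70, 0.29),
             c(0.07, 0.99, 0.11))
  m / sqrt(rowSums(m^2))
}

#' Ground truth for Beer-Lambert stain synthesis
#'
#' Bundles the stain matrix and concentration scaling used to synthesize
#' stained images via the Beer-Lambert law `I = 255 * 10^(-C M)`.
#'
#' @param stain_matrix 2 x 3 matrix of unit stain vectors in optical-density
#'   space, Hematoxylin first.
#' @param max_concentration per-stain peak concentration of the synthetic
#'   fields.
#' @return a `stain_ground_truth` object.
#' @export
stain_ground_truth <- function(stain_matrix = default_stain_matrix(),
                               max_concentration = c(1.0, 0.8)) {
  stain_matrix <- as.matrix(stain_matrix)
  assert_that(nrow(stain_matrix) == 2 && ncol(stain_matrix) == 3,
              "stain_matrix must be 2 x 3")
  assert_that(all(stain_matrix >= 0), "stain vectors must be nonnegative")
  s <- svd(stain_matrix)$d
  assert_that(s[2] > 1e-6 * s[1],
              "stain matrix is rank deficient (stains are collinear)")
  stain_matrix <- stain_matrix / sqrt(rowSums(stain_matrix^2))
  max_concentration <- per_axis(max_concentration, "max_concentration")
  assert_that(all(max_concentration >= 0), "concentrations must be >= 0")
  structure(list(stain_matrix = stain_matrix,
                 max_concentration = max_concentration,
                 od_background = 255),
            class = "stain_ground_truth")
}

# Perlin-like smooth nonnegative field in [0, 1]: coarse uniform grid,
# bicubically upsampled. Consumes the current RNG stream.
smooth_field <- function(width, height, cells = 6L) {
  g <- matrix(stats::runif(cells * cells), cells, cells)
  f <- resize_image(g, width, height, method = "bicubic")[, , 1]
  f <- f - min(f)
  if (max(f) > 0) f <- f / max(f)
  f
}

#' Synthesize a stained image from exact Beer-Lambert ground truth
#'
#' Draws two smooth nonnegative concentration fields, applies
#' `I = 255 * 10^(-C M)` channel-wise and quantises to 8 bits
#' (round-half-to-even). Pixels whose intensity quantises to <= 1 in any
#' channel are flagged as saturated: their optical density is clipped and
#' stain-recovery checks should exclude them.
#'
#' @param gt a [stain_ground_truth()] object.
#' @param width,height output dimensions in pixels.
#' @param seed integer seed.
#' @return list with `image` (`(h, w, 3)`, 0..255), `concentrations`
#'   (`(h, w, 2)`), `stain_matrix`, and logical `saturated` (`(h, w)`).
#' @export
make_he_image <- function(gt, width, height, seed = 1L) {
  assert_that(inherits(gt, "stain_ground_truth"),
              "gt must be a stain_ground_truth object")
  assert_that(width >= 8 && height >= 8, "image must be at least 8 x 8")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c1 <- smooth_field(width, height) * gt$max_concentration[1]
  c2 <- smooth_field(width, height) * gt$max_concentration[2]
  conc <- array(c(c1, c2), c(height, width, 2))
  od <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    od[, , ch] <- c1 * gt$stain_matrix[1, ch] + c2 * gt$stain_matrix[2, ch]
  }
  img <- quantize_8bit(255 * 10^(-od))
  saturated <- apply(img <= 1, c(1, 2), any)
  list(image = img, concentrations = conc, stain_matrix = gt$stain_matrix,
       saturated = saturated)
}

# save/restore the global RNG state so fixture generators are reproducible
# without clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

ellipse_polygon <- function(blob, n = 72L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(blob$rotation); st <- sin(blob$rotation)
  x <- blob$radii[1] * cos(t); y <- blob$radii[2] * sin(t)
  cbind(blob$center[1] + x * ct - y * st,
        blob$center[2] + x * st + y * ct)
}

render_slide_baseline <- function(spec) {
  w <- spec$width_px; h <- spec$height_px
  set.seed(spec$seed)
  img <- array(spec$background_gray + stats::rnorm(w * h * 3, sd = 2),
               c(h, w, 3))
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  M <- default_stain_matrix()
  for (blob in spec$tissue_blobs) {
    ct <- cos(blob$rotation); st <- sin(blob$rotation)
    u <- (xs - blob$center[1]) * ct + (ys - blob$center[2]) * st
    v <- -(xs - blob$center[1]) * st + (ys - blob$center[2]) * ct
    inside <- (u / blob$radii[1])^2 + (v / blob$radii[2])^2 <= 1
    if (!any(inside)) next
    c1 <- smooth_field(w, h) * 0.9 + 0.25   # keep blobs clearly darker
    c2 <- smooth_field(w, h) * 0.7 + 0.15
    for (ch in 1:3) {
      od <- c1 * M[1, ch] + c2 * M[2, ch]
      plane <- img[, , ch]
      plane[inside] <- 255 * 10^(-od[inside])
      img[, , ch] <- plane
    }
  }
  quantize_8bit(img)
}

#' Generate a synthetic pyramidal slide on disk
#'
#' Renders the baseline image described by `spec` (noisy near-white glass
#' plus elliptical stained tissue blobs), builds the pyramid by repeated 2x
#' area averaging, writes a tiled multi-page TIFF with resolution tags, and
#' writes a JSON sidecar (`<out_path>.json`) recording the exact ground
#' truth: level dimensions, mpp, objective power, tissue polygons and seed.
#'
#' @param spec a [slide_spec()].
#' @param out_path output TIFF path.
#' @param compression TIFF tile compression.
#' @return list with `path`, `sidecar` and the `ground_truth` record.
#' @export
make_pyramid_slide <- function(spec, out_path,
                               compression = c("deflate", "none")) {
  assert_that(inherits(spec, "slide_spec"), "spec must be a slide_spec")
  compression <- match.arg(compression)
  assert_that(dir.exists(dirname(out_path)),
              sprintf("output directory does not exist: %s", dirname(out_path)),
              "wsikit_io_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  baseline <- render_slide_baseline(spec)
  pages <- vector("list", spec$n_levels)
  pages[[1]] <- baseline
  dims <- spec_level_dims(spec)
  for (l in seq_len(spec$n_levels - 1L)) {
    pages[[l + 1L]] <- quantize_8bit(
      resize_image(pages[[l]], dims[[l + 1L]][1], dims[[l + 1L]][2],
                   method = "area"))
  }
  write_tiff_pyramid(pages, out_path, mpp = spec$mpp,
                     compression = compression)
  gt <- list(
    width_px = spec$width_px, height_px = spec$height_px,
    n_levels = spec$n_levels, mpp = spec$mpp,
    objective_power = spec$objective_power,
    background_gray = spec$background_gray, seed = spec$seed,
    level_dimensions = dims,
    level_downsamples = 2^(seq_len(spec$n_levels) - 1),
    tissue_polygons = lapply(spec$tissue_blobs, ellipse_polygon)
  )
  sidecar <- paste0(out_path, ".json")
  writeLines(jsonlite::toJSON(gt, digits = I(17), auto_unbox = TRUE), sidecar)
  list(path = out_path, sidecar = sidecar, ground_truth = gt)
}

#' Read the ground-truth sidecar of a fixture slide
#' @param path the TIFF path passed to [make_pyramid_slide()].
#' @return the ground-truth record.
#' @export
read_slide_ground_truth <- function(path) {
  sidecar <- paste0(path, ".json")
  assert_that(file.exists(sidecar),
              sprintf("no ground-truth sidecar at %s", sidecar),
              "wsikit_io_error")
  gt <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
  gt$mpp <- as.numeric(gt$mpp)
  gt$level_dimensions <- lapply(gt$level_dimensions, as.numeric)
  gt$level_downsamples <- as.numeric(gt$level_downsamples)
  gt$tissue_polygons <- lapply(gt$tissue_polygons, function(p)
    do.call(rbind, lapply(p, as.numeric)))
  gt
}

#' Generate random simple annotations
#'
#' Draws `n` random annotations inside `extent`: star-shaped polygons
#' (simple by construction) plus a configurable fraction of points, each
#' with properties `class` (sampled from `class_labels`) and `prob`
#' (uniform on 0..1).
#'
#' @param n number of annotations (>= 0).
#' @param extent bounds `c(x0, y0, x1, y1)` containing all geometry.
#' @param class_labels candidate values for the `class` property.
#' @param point_fraction fraction of annotations emitted as points.
#' @param vertices_range range of polygon vertex counts.
#' @param seed integer seed.
#' @return list of `list(geometry = wsi_geometry, properties = list)`.
#' @export
make_annotations <- function(n, extent, class_labels = 1:3,
                             point_fraction = 0.1,
                             vertices_range = c(5L, 12L), seed = 1L) {
  assert_that(is_scalar_number(n) && n >= 0, "n must be >= 0")
  assert_bounds(extent)
  assert_that(vertices_range[1] >= 4, "polygons need at least 4 vertices")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", n)
  if (n == 0) return(out)
  ext <- bounds_extent(extent)
  rmax <- 0.04 * min(ext)
  for (i in seq_len(n)) {
    cls <- sample(class_labels, 1)
    props <- list(class = cls, prob = stats::runif(1))
    if (stats::runif(1) < point_fraction) {
      g <- geom_point(stats::runif(1, extent[1], extent[3]),
                      stats::runif(1, extent[2], extent[4]))
    } else {
      cx <- stats::runif(1, extent[1] + rmax, extent[3] - rmax)
      cy <- stats::runif(1, extent[2] + rmax, extent[4] - rmax)
      k <- sample(vertices_range[1]:vertices_range[2], 1)
      # jittered regular angles: every angular gap stays below pi (k >= 4),
      # so the radial polygon is simple by construction
      ang <- 2 * pi * (seq_len(k) - 1 + stats::runif(k, 0, 0.95)) / k
      rad <- stats::runif(k, 0.25 * rmax, rmax)
      g <- geom_polygon(cbind(cx + rad * cos(ang), cy + rad * sin(ang)))
    }
    out[[i]] <- list(geometry = g, properties = props)
  }
  out
}
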