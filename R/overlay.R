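# Overlay rendering: alpha-blend prediction maps (label rasters coloured by
# a palette) or annotation outlines/fills onto a base image.

default_colormap <- function(n) {
  grDevices::col2rgb(grDevices::hcl.colors(max(n, 2), "viridis"))
}

#' Overlay predictions or annotations on an image
#'
#' For a [prediction_map()]: colours the label raster with `colormap`,
#' scales it (nearest neighbour) onto the base frame, and blends
#' `out = (1 - alpha) * base + alpha * colour` on covered cells; cells the
#' model never processed are left untouched. For a list of annotations:
#' polygons are filled (or outlined) coloured by the `color_by` property.
#'
#' @param base RGB image, 0..255, registered to the slide frame.
#' @param x a `prediction_map` or list of [annotation()]s.
#' @param alpha blend weight in `[0, 1]`.
#' @param colormap 3 x k matrix of RGB columns (one per label / class);
#'   defaults to a viridis-like palette.
#' @param base_scale base-image pixels per baseline pixel (for annotation
#'   overlays when the base is not at baseline resolution).
#' @param color_by property used to colour annotations.
#' @param fill fill annotation polygons (otherwise outline only).
#' @return blended RGB image, same shape as `base`.
#' @export
overlay <- function(base, x, alpha = 0.5, colormap = NULL,
                    base_scale = 1, color_by = "class", fill = TRUE) {
  assert_that(is_scalar_number(alpha) && alpha >= 0 && alpha <= 1,
              "alpha must be in [0, 1]")
  base <- as_image_array(base)
  if (dim(base)[3] == 1) base <- array(rep(base, 3), c(dim(base)[1:2], 3))
  if (inherits(x, "prediction_map")) {
    return(overlay_map(base, x, alpha, colormap))
  }
  if (is.list(x)) {
    return(overlay_annotations(base, x, alpha, colormap, base_scale,
                               color_by, fill))
  }
  abort("x must be a prediction_map or a list of annotations",
        "wsikit_validation_error")
}

overlay_map <- function(base, map, alpha, colormap) {
  d <- dim(base)
  # registration check: map cells times cell size must span the donor slide
  sd <- map$donor_meta$slide_dimensions
  span <- c(ncol(map$labels), nrow(map$labels)) * map$cell_size
  if (any(span < sd * 0.5) || any(span > sd * 1.5)) {
    abort("prediction map does not register to the base image frame",
          "wsikit_validation_error")
  }
  labels <- map$labels
  n_lab <- max(1, max(labels, na.rm = TRUE))
  if (is.null(colormap)) colormap <- default_colormap(n_lab)
  big_lab <- resize_image(ifelse(is.na(labels), 0L, labels),
                          d[2], d[1], method = "nearest")[, , 1]
  covered <- big_lab > 0
  out <- base
  for (ch in 1:3) {
    colour <- matrix(0, d[1], d[2])
    colour[covered] <- colormap[ch, big_lab[covered]]
    plane <- out[, , ch]
    plane[covered] <- (1 - alpha) * plane[covered] + alpha * colour[covered]
    out[, , ch] <- plane
  }
  out
}

overlay_annotations <- function(base, anns, alpha, colormap, base_scale,
                                color_by, fill) {
  d <- dim(base)
  base_scale <- per_axis(base_scale)
  vals <- vapply(anns, function(a) {
    v <- as_annotation(a)$properties[[color_by]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  levels <- sort(unique(vals[!is.na(vals)]))
  if (length(levels) == 0) levels <- "all"
  if (is.null(colormap)) colormap <- default_colormap(length(levels))
  out <- base
  for (li in seq_along(levels)) {
    sel <- which(is.na(vals) & levels[li] == "all" | vals %in% levels[li])
    polys <- lapply(anns[sel], function(a) {
      g <- as_annotation(a)$geometry
      g$coords
    })
    polys <- Filter(function(p) nrow(p) >= 3, polys)
    if (length(polys) == 0) next
    m <- rasterize_polygons(polys, d[2], d[1], scale = base_scale)
    if (!fill) {
      er <- EBImage::erode(m, EBImage::makeBrush(3, "box"))
      m <- m & !(er > 0.5)
    }
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[m] <- (1 - alpha) * plane[m] + alpha * colormap[ch, li]
      out[, , ch] <- plane
    }
  }
  out
}

#' Write an image array to PNG
#' @param img image array, 0..255.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  img <- as_image_array(img)
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}
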