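# Otsu tissue/background masking, exposed as a virtual reader so mask and
# tissue slide can be read synchronously with identical arguments.

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the 8-bit threshold maximising the between-class variance
#' (equivalently, minimising the intra-class intensity variance). Pixels with
#' value `<= t` form one class. When several thresholds tie, the smallest is
#' returned.
#'
#' @param histogram numeric vector of 256 counts (values 0..255).
#' @return integer threshold in 0..255.
#' @export
otsu_threshold <- function(histogram) {
  assert_that(is.numeric(histogram) && length(histogram) == 256 &&
                all(histogram >= 0), "histogram must be 256 nonnegative counts")
  total <- sum(histogram)
  assert_that(total > 0, "histogram is empty")
  if (sum(histogram > 0) < 2) {
    abort("degenerate histogram: all mass in a single bin",
          "wsikit_degenerate_error")
  }
  p <- histogram / total
  v <- 0:255
  w0 <- cumsum(p)                 # class 0 = bins 0..t
  mu0 <- cumsum(p * v)
  mu_t <- mu0[256]
  # between-class variance at each candidate split t = 0..254
  w <- w0[1:255]
  m <- mu0[1:255]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  which.max(sigma_b) - 1L
}

#' Tissue masker configuration
#'
#' @param luminosity_first convert to a luminosity channel (min over RGB,
#'   robust to stain hue) before thresholding.
#' @param kernel_px structuring-element side for morphological closing, in
#'   mask-resolution pixels; `NULL` scales with the mask downsample.
#' @param min_region_px remove tissue components smaller than this.
#' @param min_hole_px fill background holes smaller than this. Defaults for
#'   both are `kernel_px^2`.
#' @return a `masker_config`.
#' @export
masker_config <- function(luminosity_first = TRUE, kernel_px = NULL,
                          min_region_px = NULL, min_hole_px = NULL) {
  if (!is.null(kernel_px)) {
    assert_that(is_scalar_number(kernel_px) && kernel_px >= 1,
                "kernel_px must be >= 1")
  }
  structure(list(luminosity_first = isTRUE(luminosity_first),
                 kernel_px = kernel_px, min_region_px = min_region_px,
                 min_hole_px = min_hole_px),
            class = "masker_config")
}

drop_small_components <- function(mask, min_px) {
  if (min_px <= 0 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab)
  small <- which(sizes < min_px)
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

# a hole is a background component that does not touch the image border
fill_small_holes <- function(mask, min_px) {
  if (min_px <= 0 || all(mask)) return(mask)
  lab <- EBImage::bwlabel(!mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab)
  fill <- setdiff(which(sizes < min_px), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

#' Build a tissue mask as a virtual reader
#'
#' Reads a thumbnail at `res`, converts to luminosity, thresholds with
#' Otsu's method (tissue = the darker class), applies morphological closing
#' and removes small components and holes, then wraps the binary mask with
#' the slide's metadata via [as_virtual()] so mask reads stay synchronised
#' with tissue reads. A blank slide (degenerate histogram) yields an
#' all-background mask with a warning.
#'
#' @param reader tissue `wsi_reader`.
#' @param config a [masker_config()].
#' @param res mask resolution; default mpp 32 when the slide has mpp
#'   metadata, else 1/32 of baseline.
#' @return virtual label `wsi_reader` with values 0 (background) / 1
#'   (tissue).
#' @export
make_mask <- function(reader, config = masker_config(), res = NULL) {
  if (is.null(res)) {
    res <- if (!is.null(reader$meta$mpp)) {
      resolution(32, "mpp")
    } else {
      resolution(1 / 32, "baseline")
    }
  }
  thumb <- slide_thumbnail(reader, res)
  lum <- if (config$luminosity_first && dim(thumb)[3] >= 3) {
    pmin(thumb[, , 1], thumb[, , 2], thumb[, , 3])
  } else {
    thumb[, , 1]
  }
  h <- tabulate(pmin(pmax(floor(lum), 0), 255) + 1L, nbins = 256L)
  mask <- tryCatch({
    t <- otsu_threshold(h)
    lum <= t
  }, wsikit_degenerate_error = function(e) {
    warning("blank slide: degenerate histogram, returning all-background mask",
            call. = FALSE)
    matrix(FALSE, nrow(lum), ncol(lum))
  })
  kernel_px <- config$kernel_px
  if (is.null(kernel_px)) {
    ds <- mean(reader$meta$slide_dimensions / c(ncol(mask), nrow(mask)))
    power <- if (is.null(reader$meta$objective_power)) 40 else
      reader$meta$objective_power
    kernel_px <- max(1L, round(power / ds * 2))
  }
  min_region <- if (is.null(config$min_region_px)) kernel_px^2 else
    config$min_region_px
  min_hole <- if (is.null(config$min_hole_px)) kernel_px^2 else
    config$min_hole_px
  if (any(mask) && kernel_px > 1) {
    brush <- EBImage::makeBrush(2 * floor(kernel_px / 2) + 1, shape = "box")
    mask <- EBImage::closing(mask, brush) > 0.5
  }
  mask <- drop_small_components(mask, min_region)
  mask <- fill_small_holes(mask, min_hole)
  as_virtual(mask * 1, reader$meta, interpretation = "label")
}
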