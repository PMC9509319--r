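# Zoomify tile pyramids: tiers double from a single-tile thumbnail up to
# the baseline, tiles are numbered tier-major (tier 0 first) and row-major
# within a tier, grouped 256 per TileGroup directory. Edge tiles are
# cropped, not padded (the viewer convention).

#' Zoomify tile pyramid specification
#'
#' Tier `t` (0-based, smallest first) has dimensions
#' `ceiling(baseline / 2^(n_tiers - 1 - t))`; the smallest tier fits in one
#' tile. `n_tiers = max(1, ceil(log2(max_dim / tile_size)) + 1)`.
#'
#' @param meta a [wsi_meta()] (or anything with `slide_dimensions`).
#' @param tile_size tile side in pixels.
#' @return a `tile_pyramid_spec` with `tier_dims` (list, smallest first),
#'   `tier_tiles` (tiles per tier, (nx, ny)), and `total_tiles`.
#' @export
tile_pyramid_spec <- function(meta, tile_size = 256L) {
  assert_that(tile_size >= 1, "tile_size must be >= 1")
  sd <- meta$slide_dimensions
  n_tiers <- max(1, ceiling(log2(max(sd) / tile_size)) + 1)
  tier_dims <- lapply(seq_len(n_tiers) - 1L, function(t) {
    ceiling(sd / 2^(n_tiers - 1 - t))
  })
  tier_tiles <- lapply(tier_dims, function(d) ceiling(d / tile_size))
  structure(list(tile_size = as.integer(tile_size),
                 slide_dimensions = sd,
                 n_tiers = as.integer(n_tiers),
                 tier_dims = tier_dims, tier_tiles = tier_tiles,
                 total_tiles = sum(vapply(tier_tiles, prod, numeric(1)))),
            class = "tile_pyramid_spec")
}

#' Zoomify tile number and group
#'
#' Tiles are numbered from tier 0 upward, row-major within each tier;
#' `group = floor(number / 256)` names the `TileGroup{group}` directory.
#'
#' @param spec a [tile_pyramid_spec()].
#' @param tier tier index (0 = smallest).
#' @param x,y tile column and row within the tier (0-based).
#' @return list with `number` and `group`.
#' @export
tile_index <- function(spec, tier, x, y) {
  assert_that(tier >= 0 && tier < spec$n_tiers,
              sprintf("tier %d out of range", tier))
  nt <- spec$tier_tiles[[tier + 1L]]
  assert_that(x >= 0 && x < nt[1] && y >= 0 && y < nt[2],
              sprintf("tile (%d, %d) outside tier %d grid %dx%d",
                      x, y, tier, nt[1], nt[2]))
  before <- if (tier == 0) 0 else
    sum(vapply(spec$tier_tiles[seq_len(tier)], prod, numeric(1)))
  number <- before + y * nt[1] + x
  list(number = as.integer(number), group = as.integer(number %/% 256))
}

#' Read one Zoomify tile
#'
#' The tile equals [read_bounds()] of the corresponding baseline region
#' scaled to the tier; edge tiles are cropped to the tier boundary.
#'
#' @param reader a `wsi_reader`.
#' @param spec a [tile_pyramid_spec()].
#' @inheritParams tile_index
#' @return image of at most `tile_size` per side.
#' @export
get_tile <- function(reader, spec, tier, x, y) {
  idx <- tile_index(spec, tier, x, y)  # validates the index
  ts <- spec$tile_size
  td <- spec$tier_dims[[tier + 1L]]
  scale <- 2^(spec$n_tiers - 1 - tier)
  tw <- min(ts, td[1] - x * ts)
  th <- min(ts, td[2] - y * ts)
  bounds <- c(x * ts, y * ts, x * ts + tw, y * ts + th) * scale
  bounds[3] <- min(bounds[3], spec$slide_dimensions[1])
  bounds[4] <- min(bounds[4], spec$slide_dimensions[2])
  read_region_core(reader, bounds, c(tw, th), c(1 / scale, 1 / scale))
}

#' Write a Zoomify directory tree
#'
#' Writes `TileGroup{g}/{tier}-{x}-{y}.jpg` for every tile plus an
#' `ImageProperties.xml` declaring the slide dimensions, tile size and tile
#' count. Re-running produces the same file set.
#'
#' @param reader a `wsi_reader`.
#' @param out_dir output directory (created if needed).
#' @param tile_size tile side.
#' @param quality JPEG quality in 0..1.
#' @return the spec, invisibly.
#' @export
dump_tiles <- function(reader, out_dir, tile_size = 256L, quality = 0.85) {
  spec <- tile_pyramid_spec(reader$meta, tile_size)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir),
              sprintf("cannot create output directory %s", out_dir),
              "wsikit_io_error")
  for (tier in seq_len(spec$n_tiers) - 1L) {
    nt <- spec$tier_tiles[[tier + 1L]]
    for (y in seq_len(nt[2]) - 1L) {
      for (x in seq_len(nt[1]) - 1L) {
        idx <- tile_index(spec, tier, x, y)
        gdir <- file.path(out_dir, sprintf("TileGroup%d", idx$group))
        dir.create(gdir, showWarnings = FALSE)
        tile <- get_tile(reader, spec, tier, x, y)
        path <- file.path(gdir, sprintf("%d-%d-%d.jpg", tier, x, y))
        ok <- tryCatch({
          jpeg::writeJPEG(clamp(tile, 0, 255) / 255, path, quality = quality)
          TRUE
        }, error = function(e) {
          abort(sprintf("cannot write tile %s: %s", path,
                        conditionMessage(e)), "wsikit_io_error")
        })
      }
    }
  }
  xml <- sprintf(paste0(
    '<IMAGE_PROPERTIES WIDTH="%d" HEIGHT="%d" NUMTILES="%d" NUMIMAGES="1"',
    ' VERSION="1.8" TILESIZE="%d" />'),
    spec$slide_dimensions[1], spec$slide_dimensions[2], spec$total_tiles,
    spec$tile_size)
  writeLines(xml, file.path(out_dir, "ImageProperties.xml"))
  invisible(spec)
}
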