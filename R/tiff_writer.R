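# Minimal classic-TIFF writer for the fixture generator: little-endian,
# tiled RGB pages, deflate (Adobe, zlib streams) or uncompressed, with
# X/YResolution + ResolutionUnit tags carrying microns-per-pixel. Exists
# because the installed 'tiff' package can write neither tiled pages nor
# resolution tags; files written here are read back through tiff::readTIFF
# (libtiff), which is the package's only TIFF *reader*.

TIFF_SHORT <- 3L
TIFF_LONG <- 4L
TIFF_RATIONAL <- 5L

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# mpp (um/px) -> pixels-per-centimetre rational (numerator, denominator).
# denominator = round(mpp * 1e5) so that mpp values with <= 5 decimals
# round-trip exactly: mpp_back = 1e4 / (num/den) = round(mpp * 1e5) / 1e5.
mpp_to_rational <- function(mpp) c(1e9, round(mpp * 1e5))

tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4)
  pad <- raw(4 - length(value_raw))
  c(u16(tag), u16(type), u32(count), value_raw, pad)
}

# Encode one page worth of tile data; img is (h, w, 3) in 0..255.
encode_tiles <- function(img, tile_size, compression) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ntx <- ceiling(w / tile_size)
  nty <- ceiling(h / tile_size)
  tiles <- vector("list", ntx * nty)
  k <- 1L
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      y0 <- (ty - 1L) * tile_size + 1L
      x0 <- (tx - 1L) * tile_size + 1L
      iy <- clamp(y0:(y0 + tile_size - 1L), 1L, h)   # edge-replicate padding
      ix <- clamp(x0:(x0 + tile_size - 1L), 1L, w)
      tile <- img[iy, ix, , drop = FALSE]
      bytes <- as.raw(as.integer(aperm(tile, c(3, 2, 1))))  # RGBRGB..., rows
      if (compression == "deflate") bytes <- memCompress(bytes, type = "gzip")
      tiles[[k]] <- bytes
      k <- k + 1L
    }
  }
  tiles
}

#' Write a multi-page tiled TIFF pyramid
#'
#' Writes a list of RGB images (baseline first, then successively
#' downsampled levels) as a tiled multi-page TIFF with resolution tags
#' encoding the microns-per-pixel of each page. Pages after the first are
#' flagged as reduced-resolution subfiles.
#'
#' @param pages list of `(h, w, 3)` arrays, values 0..255.
#' @param path output file path.
#' @param mpp baseline microns-per-pixel, length 1 or 2 `(x, y)`.
#' @param compression `"deflate"` (zlib) or `"none"`.
#' @param tile_size tile side in pixels (multiple of 16).
#' @return `path`, invisibly.
#' @export
write_tiff_pyramid <- function(pages, path, mpp, compression = c("deflate", "none"),
                               tile_size = 256L) {
  compression <- match.arg(compression)
  assert_that(length(pages) >= 1L, "at least one page required")
  assert_that(tile_size %% 16 == 0 && tile_size > 0,
              "tile_size must be a positive multiple of 16")
  mpp <- per_axis(mpp, "mpp")
  base_dim <- dim(as_image_array(pages[[1]]))

  chunks <- list()
  pos <- 8L  # after header
  alloc <- function(bytes) {
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, raw(1))  # word align
    chunks[[length(chunks) + 1L]] <<- bytes
    off <- pos
    pos <<- pos + length(bytes)
    off
  }

  ifd_offsets <- integer(length(pages))
  for (p in seq_along(pages)) {
    img <- as_image_array(pages[[p]])
    d <- dim(img)
    assert_that(d[3] == 3L, "pyramid pages must be RGB")
    # per-page mpp scales with the downsample relative to the baseline
    page_mpp <- mpp * (base_dim[2] / d[2])
    tiles <- encode_tiles(img, tile_size, compression)
    tile_offsets <- vapply(tiles, alloc, integer(1))
    tile_counts <- vapply(tiles, length, integer(1))

    bps_off <- alloc(u16(c(8L, 8L, 8L)))
    xr <- mpp_to_rational(page_mpp[1]); yr <- mpp_to_rational(page_mpp[2])
    xres_off <- alloc(u32(xr))
    yres_off <- alloc(u32(yr))
    n_tiles <- length(tiles)
    if (n_tiles > 1L) {
      to_off <- alloc(u32(tile_offsets))
      tc_off <- alloc(u32(tile_counts))
    }

    entries <- list(
      tiff_entry(254L, TIFF_LONG, 1L, u32(if (p == 1L) 0L else 1L)),
      tiff_entry(256L, TIFF_LONG, 1L, u32(d[2])),
      tiff_entry(257L, TIFF_LONG, 1L, u32(d[1])),
      tiff_entry(258L, TIFF_SHORT, 3L, u32(bps_off)),
      tiff_entry(259L, TIFF_SHORT, 1L,
                 u16(if (compression == "deflate") 8L else 1L)),
      tiff_entry(262L, TIFF_SHORT, 1L, u16(2L)),  # RGB
      tiff_entry(277L, TIFF_SHORT, 1L, u16(3L)),
      tiff_entry(282L, TIFF_RATIONAL, 1L, u32(xres_off)),
      tiff_entry(283L, TIFF_RATIONAL, 1L, u32(yres_off)),
      tiff_entry(284L, TIFF_SHORT, 1L, u16(1L)),  # chunky
      tiff_entry(296L, TIFF_SHORT, 1L, u16(3L)),  # centimetre
      tiff_entry(322L, TIFF_LONG, 1L, u32(tile_size)),
      tiff_entry(323L, TIFF_LONG, 1L, u32(tile_size)),
      tiff_entry(324L, TIFF_LONG, n_tiles,
                 if (n_tiles > 1L) u32(to_off) else u32(tile_offsets)),
      tiff_entry(325L, TIFF_LONG, n_tiles,
                 if (n_tiles > 1L) u32(tc_off) else u32(tile_counts))
    )
    ifd <- c(u16(length(entries)), do.call(c, entries), u32(0L))
    ifd_offsets[p] <- alloc(ifd)
  }

  # patch next-IFD pointers: each IFD's trailing 4 bytes point at the next
  blob <- do.call(c, chunks)
  header <- c(charToRaw("II"), u16(42L), u32(ifd_offsets[1]))
  file_raw <- c(header, blob)
  for (p in seq_along(pages)) {
    nxt <- if (p < length(pages)) ifd_offsets[p + 1L] else 0L
    ifd_len <- 2L + 12L * 15L + 4L
    ptr_at <- ifd_offsets[p] + ifd_len - 4L  # 0-based offset of next pointer
    file_raw[(ptr_at + 1L):(ptr_at + 4L)] <- u32(nxt)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(file_raw, con)
  invisible(path)
}
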