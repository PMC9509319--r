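# Minimal planar geometry: points, line strings, linear rings and simple
# polygons in the baseline slide frame, with OGC Well-Known Binary
# serialisation. No coordinate reference systems -- slide pixels only.

GEOM_TYPES <- c("POINT", "LINESTRING", "POLYGON")

new_geometry <- function(type, coords) {
  structure(list(type = type, coords = coords), class = "wsi_geometry")
}

#' Geometry constructors
#'
#' Build the geometry primitives understood by the annotation store: points,
#' line strings, closed linear rings (a closed line string with no area) and
#' simple polygons with a single outer ring. Polygon rings are stored closed
#' (first vertex repeated as the last); `geom_polygon()` closes an open ring.
#'
#' @param x,y point coordinates.
#' @param coords n x 2 numeric matrix of vertices.
#' @return a `wsi_geometry` object.
#' @export
geom_point <- function(x, y) {
  assert_that(is_scalar_number(x) && is_scalar_number(y),
              "point coordinates must be finite scalars")
  new_geometry("POINT", matrix(c(x, y), 1))
}

#' @rdname geom_point
#' @export
geom_linestring <- function(coords) {
  coords <- check_coords(coords, min_n = 2L)
  new_geometry("LINESTRING", coords)
}

#' @rdname geom_point
#' @export
geom_ring <- function(coords) {
  coords <- check_coords(coords, min_n = 3L)
  coords <- close_ring(coords)
  new_geometry("LINESTRING", coords)
}

#' @rdname geom_point
#' @export
geom_polygon <- function(coords) {
  coords <- check_coords(coords, min_n = 3L)
  coords <- close_ring(coords)
  new_geometry("POLYGON", coords)
}

check_coords <- function(coords, min_n) {
  coords <- as.matrix(coords)
  assert_that(ncol(coords) == 2L && nrow(coords) >= min_n &&
                all(is.finite(coords)),
              sprintf("coordinates must be a finite n x 2 matrix, n >= %d",
                      min_n))
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  coords
}

close_ring <- function(coords) {
  n <- nrow(coords)
  if (coords[1, 1] != coords[n, 1] || coords[1, 2] != coords[n, 2]) {
    coords <- rbind(coords, coords[1, ])
  }
  coords
}

#' @export
print.wsi_geometry <- function(x, ...) {
  cat(sprintf("<%s, %d vertices>\n", x$type, nrow(x$coords)))
  invisible(x)
}

geom_type <- function(g) g$type

#' Bounding box of a geometry
#' @param g a `wsi_geometry`.
#' @return c(x0, y0, x1, y1) (min/max, degenerate for points).
#' @export
geom_bbox <- function(g) {
  c(min(g$coords[, 1]), min(g$coords[, 2]),
    max(g$coords[, 1]), max(g$coords[, 2]))
}

bbox_intersects <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

# --- predicates -------------------------------------------------------------

# even-odd point-in-polygon; boundary points count as inside
point_in_polygon <- function(x, y, coords) {
  px <- coords[, 1]; py <- coords[, 2]
  n <- nrow(coords)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1L }
  j <- c(n, seq_len(n - 1L))
  on_edge <- any(point_on_segment(x, y, px, py, px[j], py[j]))
  if (on_edge) return(TRUE)
  crosses <- ((py <= y) & (py[j] > y)) | ((py[j] <= y) & (py > y))
  if (!any(crosses)) return(FALSE)
  i <- which(crosses)
  xint <- px[i] + (y - py[i]) / (py[j][i] - py[i]) * (px[j][i] - px[i])
  sum(xint > x) %% 2 == 1
}

point_on_segment <- function(x, y, x1, y1, x2, y2, eps = 1e-9) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  within <- x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
    y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
  abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) & within
}

segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on <- function(a, b, c) {
    abs(d(a, b, c)) <= eps * (abs(b[1] - a[1]) + abs(b[2] - a[2]) + 1) &&
      c[1] >= min(a[1], b[1]) - eps && c[1] <= max(a[1], b[1]) + eps &&
      c[2] >= min(a[2], b[2]) - eps && c[2] <= max(a[2], b[2]) + eps
  }
  on(p3, p4, p1) || on(p3, p4, p2) || on(p1, p2, p3) || on(p1, p2, p4)
}

edges_of <- function(coords) {
  n <- nrow(coords)
  lapply(seq_len(n - 1L), function(i) rbind(coords[i, ], coords[i + 1L, ]))
}

any_edge_intersection <- function(ca, cb) {
  ea <- edges_of(ca); eb <- edges_of(cb)
  for (sa in ea) for (sb in eb) {
    if (segments_intersect(sa[1, ], sa[2, ], sb[1, ], sb[2, ])) return(TRUE)
  }
  FALSE
}

#' Exact geometric intersection test
#'
#' True when the two geometries share at least one point. Polygons are
#' treated as filled regions, line strings as one-dimensional sets.
#'
#' @param a,b `wsi_geometry` objects.
#' @export
geoms_intersect <- function(a, b) {
  if (!bbox_intersects(geom_bbox(a), geom_bbox(b))) return(FALSE)
  ta <- geom_type(a); tb <- geom_type(b)
  if (ta == "POINT" && tb == "POINT") {
    return(all(a$coords[1, ] == b$coords[1, ]))
  }
  if (ta == "POINT") return(geoms_intersect(b, a))
  if (tb == "POINT") {
    p <- b$coords[1, ]
    if (ta == "POLYGON") return(point_in_polygon(p[1], p[2], a$coords))
    e <- edges_of(a$coords)
    return(any(vapply(e, function(s)
      point_on_segment(p[1], p[2], s[1, 1], s[1, 2], s[2, 1], s[2, 2]),
      logical(1))))
  }
  if (any_edge_intersection(a$coords, b$coords)) return(TRUE)
  # containment without edge crossing
  if (ta == "POLYGON" && point_in_polygon(b$coords[1, 1], b$coords[1, 2], a$coords)) return(TRUE)
  if (tb == "POLYGON" && point_in_polygon(a$coords[1, 1], a$coords[1, 2], b$coords)) return(TRUE)
  FALSE
}

#' Is a ring or line string simple (non-self-intersecting)?
#'
#' Checks that no pair of non-adjacent segments intersects. Closed rings may
#' share their first/last vertex.
#'
#' @param g a `wsi_geometry`.
#' @export
geom_is_simple <- function(g) {
  if (geom_type(g) == "POINT") return(TRUE)
  coords <- g$coords
  n <- nrow(coords)
  closed <- all(coords[1, ] == coords[n, ])
  m <- n - 1L  # number of segments
  if (m < 2L) return(TRUE)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (j == i + 1L) next
      if (closed && i == 1L && j == m) next
      if (segments_intersect(coords[i, ], coords[i + 1L, ],
                             coords[j, ], coords[j + 1L, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# --- WKB --------------------------------------------------------------------

WKB_CODE <- c(POINT = 1L, LINESTRING = 2L, POLYGON = 3L)

#' Serialise geometry to Well-Known Binary
#'
#' Encodes a geometry as little-endian OGC WKB, optionally wrapped in a zlib
#' (RFC 1950) deflate stream. Round trips are lossless: coordinates are
#' written as IEEE-754 doubles.
#'
#' @param g a `wsi_geometry`.
#' @param compress deflate-compress the WKB payload.
#' @return raw vector.
#' @export
geom_to_wkb <- function(g, compress = FALSE) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(1L), con)  # little endian
  writeBin(WKB_CODE[[geom_type(g)]], con, size = 4, endian = "little")
  coords <- g$coords
  if (geom_type(g) == "POINT") {
    writeBin(as.numeric(coords[1, ]), con, size = 8, endian = "little")
  } else if (geom_type(g) == "LINESTRING") {
    writeBin(nrow(coords), con, size = 4, endian = "little")
    writeBin(as.numeric(t(coords)), con, size = 8, endian = "little")
  } else {
    writeBin(1L, con, size = 4, endian = "little")  # one ring
    writeBin(nrow(coords), con, size = 4, endian = "little")
    writeBin(as.numeric(t(coords)), con, size = 8, endian = "little")
  }
  out <- rawConnectionValue(con)
  if (compress) memCompress(out, type = "gzip") else out
}

#' @rdname geom_to_wkb
#' @param bytes raw vector holding WKB, plain or deflate-compressed.
#' @export
geom_from_wkb <- function(bytes) {
  assert_that(is.raw(bytes) && length(bytes) >= 2,
              "WKB payload is empty or truncated", "wsikit_decode_error")
  # zlib streams start 0x78; plain little-endian WKB starts 0x01
  if (bytes[1] != as.raw(1L)) {
    bytes <- tryCatch(memDecompress(bytes, type = "gzip"),
                      error = function(e)
                        abort("not WKB and not a zlib stream",
                              "wsikit_decode_error"))
  }
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  endian <- if (readBin(con, "raw", 1) == as.raw(1)) "little" else "big"
  code <- readBin(con, "integer", 1, size = 4, endian = endian)
  type <- names(WKB_CODE)[match(code, WKB_CODE)]
  assert_that(!is.na(type), sprintf("unsupported WKB geometry code %d", code),
              "wsikit_decode_error")
  read_pts <- function(n) {
    v <- readBin(con, "numeric", 2 * n, size = 8, endian = endian)
    assert_that(length(v) == 2 * n, "truncated WKB payload",
                "wsikit_decode_error")
    matrix(v, ncol = 2, byrow = TRUE)
  }
  if (type == "POINT") {
    p <- read_pts(1)
    return(geom_point(p[1, 1], p[1, 2]))
  }
  if (type == "LINESTRING") {
    n <- readBin(con, "integer", 1, size = 4, endian = endian)
    return(new_geometry("LINESTRING", read_pts(n)))
  }
  n_rings <- readBin(con, "integer", 1, size = 4, endian = endian)
  assert_that(n_rings == 1L, "only single-ring polygons are supported",
              "wsikit_decode_error")
  n <- readBin(con, "integer", 1, size = 4, endian = endian)
  new_geometry("POLYGON", read_pts(n))
}

geoms_equal <- function(a, b) {
  identical(geom_type(a), geom_type(b)) && identical(a$coords, b$coords)
}
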