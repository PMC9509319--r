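# Annotation stores: a mutable mapping of key -> (geometry, properties)
# with spatial queries. Two interchangeable backends behind one S3 surface:
#   * "memory": an environment-backed hash map with linear-scan queries,
#     suited to small sets;
#   * "database": a single-file SQLite schema -- one `annotations` table
#     (key, properties JSON, WKB geometry blob, centroid) plus an R-Tree
#     virtual table of bounding boxes for sublinear window queries. Points
#     store no WKB at all: their coordinates live entirely in the R-Tree
#     row and are reconstructed from it.

#' Create an annotation
#'
#' @param geometry a `wsi_geometry` (see [geom_point()]).
#' @param properties JSON-serialisable named list.
#' @return an `annotation` object.
#' @export
annotation <- function(geometry, properties = list()) {
  assert_that(inherits(geometry, "wsi_geometry"), "geometry must be a wsi_geometry")
  assert_that(is.list(properties), "properties must be a list")
  if (length(properties)) {
    assert_that(!is.null(names(properties)) && all(nzchar(names(properties))),
                "properties must be named")
  }
  structure(list(geometry = geometry, properties = properties),
            class = "wsi_annotation")
}

as_annotation <- function(x) {
  if (inherits(x, "wsi_annotation")) return(x)
  if (is.list(x) && !is.null(x$geometry)) {
    return(annotation(x$geometry, if (is.null(x$properties)) list() else
      x$properties))
  }
  abort("not an annotation", "wsikit_validation_error")
}

#' Open an annotation store
#'
#' Both backends satisfy the same mapping contract (insert, get, delete,
#' iterate keys, length) and the same query semantics; the database backend
#' persists across reopenings of the same path.
#'
#' @param backend `"memory"` or `"database"` (SQLite single file).
#' @param path database file path (`":memory:"` for a transient database).
#' @param compress deflate-compress WKB geometry blobs (database backend).
#' @return an `annotation_store`.
#' @export
open_store <- function(backend = c("memory", "database"), path = NULL,
                       compress = FALSE) {
  backend <- match.arg(backend)
  if (backend == "memory") {
    store <- structure(list(env = new.env(parent = emptyenv())),
                       class = c("memory_store", "annotation_store"))
    return(store)
  }
  if (is.null(path)) path <- ":memory:"
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path),
                  error = function(e)
                    abort(sprintf("cannot open database %s: %s", path,
                                  conditionMessage(e)),
                          "wsikit_format_error"))
  ok <- tryCatch({
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS annotations (
        key TEXT PRIMARY KEY, geom_type TEXT NOT NULL,
        properties TEXT NOT NULL, geometry BLOB,
        cx REAL NOT NULL, cy REAL NOT NULL,
        x0 REAL NOT NULL, y0 REAL NOT NULL,
        x1 REAL NOT NULL, y1 REAL NOT NULL)")
    DBI::dbExecute(con, "CREATE VIRTUAL TABLE IF NOT EXISTS rtree
        USING rtree(id, min_x, max_x, min_y, max_y)")
    DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS rtree_key (
        id INTEGER PRIMARY KEY, key TEXT UNIQUE NOT NULL)")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    DBI::dbDisconnect(con)
    abort(sprintf("corrupt or incompatible database: %s", path),
          "wsikit_format_error")
  }
  structure(list(con = con, path = path, compress = compress),
            class = c("db_store", "annotation_store"))
}

#' Close a store (database connections are released)
#' @param store an `annotation_store`.
#' @export
close_store <- function(store) {
  if (inherits(store, "db_store")) DBI::dbDisconnect(store$con)
  invisible(NULL)
}

new_store_key <- function() {
  # UUID4-format random key
  b <- sample.int(16L, 16L, replace = TRUE) - 1L
  hx <- sprintf("%x", b)
  paste0(paste(hx[1:8], collapse = ""), "-", paste(hx[9:12], collapse = ""),
         "-4", paste(hx[13:15], collapse = ""), "-",
         sprintf("%x", 8L + (b[16] %% 4L)),
         paste(sprintf("%x", sample.int(16L, 11L, replace = TRUE) - 1L),
               collapse = ""))
}

# --- mapping contract -------------------------------------------------------

#' Store mapping operations
#'
#' `store_insert()` adds (or overwrites) an annotation and returns its key;
#' `store_get()` retrieves one (missing keys raise a key error);
#' `store_delete()` removes one; `store_keys()` lists all keys;
#' `store_length()` counts annotations.
#'
#' @param store an `annotation_store`.
#' @param ann an [annotation()].
#' @param key optional key; autogenerated when absent.
#' @export
store_insert <- function(store, ann, key = NULL) UseMethod("store_insert")

#' @rdname store_insert
#' @export
store_get <- function(store, key) UseMethod("store_get")

#' @rdname store_insert
#' @export
store_delete <- function(store, key) UseMethod("store_delete")

#' @rdname store_insert
#' @export
store_keys <- function(store) UseMethod("store_keys")

#' @rdname store_insert
#' @export
store_length <- function(store) UseMethod("store_length")

#' @export
length.annotation_store <- function(x) store_length(x)

missing_key <- function(key) {
  abort(sprintf("no annotation with key '%s'", key), "wsikit_key_error")
}

#' @export
store_insert.memory_store <- function(store, ann, key = NULL) {
  ann <- as_annotation(ann)
  if (is.null(key)) key <- new_store_key()
  assign(key, ann, envir = store$env)
  key
}

#' @export
store_get.memory_store <- function(store, key) {
  if (!exists(key, envir = store$env, inherits = FALSE)) missing_key(key)
  get(key, envir = store$env, inherits = FALSE)
}

#' @export
store_delete.memory_store <- function(store, key) {
  if (!exists(key, envir = store$env, inherits = FALSE)) missing_key(key)
  rm(list = key, envir = store$env)
  invisible(key)
}

#' @export
store_keys.memory_store <- function(store) ls(store$env, sorted = FALSE)

#' @export
store_length.memory_store <- function(store) length(ls(store$env))

#' @export
store_insert.db_store <- function(store, ann, key = NULL) {
  ann <- as_annotation(ann)
  if (is.null(key)) key <- new_store_key()
  g <- ann$geometry
  bb <- geom_bbox(g)
  cx <- mean(g$coords[, 1]); cy <- mean(g$coords[, 2])
  blob <- if (geom_type(g) == "POINT") list(NULL) else
    list(geom_to_wkb(g, compress = store$compress))
  props <- as.character(jsonlite::toJSON(ann$properties, digits = I(17),
                                         auto_unbox = TRUE))
  DBI::dbExecute(store$con,
    "INSERT OR REPLACE INTO annotations
     (key, geom_type, properties, geometry, cx, cy, x0, y0, x1, y1)
     VALUES (?,?,?,?,?,?,?,?,?,?)",
    params = list(key, geom_type(g), props, blob, cx, cy,
                  bb[1], bb[2], bb[3], bb[4]))
  row <- DBI::dbGetQuery(store$con,
    "INSERT INTO rtree_key (key) VALUES (?)
     ON CONFLICT(key) DO UPDATE SET key = key RETURNING id",
    params = list(key))
  DBI::dbExecute(store$con,
    "INSERT OR REPLACE INTO rtree (id, min_x, max_x, min_y, max_y)
     VALUES (?,?,?,?,?)",
    params = list(row$id[1], bb[1], bb[3], bb[2], bb[4]))
  key
}

db_row_to_annotation <- function(row) {
  props <- jsonlite::fromJSON(row$properties, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  g <- if (row$geom_type == "POINT") {
    geom_point(row$cx, row$cy)
  } else {
    geom_from_wkb(row$geometry[[1]])
  }
  annotation(g, props)
}

#' @export
store_get.db_store <- function(store, key) {
  row <- DBI::dbGetQuery(store$con,
    "SELECT key, geom_type, properties, geometry, cx, cy
     FROM annotations WHERE key = ?", params = list(key))
  if (nrow(row) == 0) missing_key(key)
  db_row_to_annotation(row[1, ])
}

#' @export
store_delete.db_store <- function(store, key) {
  row <- DBI::dbGetQuery(store$con, "SELECT id FROM rtree_key WHERE key = ?",
                         params = list(key))
  n <- DBI::dbExecute(store$con, "DELETE FROM annotations WHERE key = ?",
                      params = list(key))
  if (n == 0) missing_key(key)
  if (nrow(row) > 0) {
    DBI::dbExecute(store$con, "DELETE FROM rtree WHERE id = ?",
                   params = list(row$id[1]))
    DBI::dbExecute(store$con, "DELETE FROM rtree_key WHERE id = ?",
                   params = list(row$id[1]))
  }
  invisible(key)
}

#' @export
store_keys.db_store <- function(store) {
  DBI::dbGetQuery(store$con, "SELECT key FROM annotations")$key
}

#' @export
store_length.db_store <- function(store) {
  DBI::dbGetQuery(store$con, "SELECT COUNT(*) AS n FROM annotations")$n
}

# --- queries ----------------------------------------------------------------

#' Bounding-box query
#'
#' Returns the keys of all annotations whose bounding box intersects
#' `bounds`. The database backend answers from the R-Tree index; the memory
#' backend scans.
#'
#' @param store an `annotation_store`.
#' @param bounds `c(x0, y0, x1, y1)`.
#' @return character vector of keys.
#' @export
bquery <- function(store, bounds) UseMethod("bquery")

#' @export
bquery.memory_store <- function(store, bounds) {
  assert_bounds(bounds)
  keys <- store_keys(store)
  keep <- vapply(keys, function(k) {
    bbox_intersects(geom_bbox(store_get(store, k)$geometry), bounds)
  }, logical(1))
  keys[keep]
}

#' @export
bquery.db_store <- function(store, bounds) {
  assert_bounds(bounds)
  # the R-Tree stores 32-bit floats widened to contain the true box, so it
  # is a superset prefilter; candidates are re-checked against the exact
  # 64-bit bounds kept in the annotations table
  DBI::dbGetQuery(store$con,
    "SELECT a.key FROM rtree rt
       JOIN rtree_key rk ON rk.id = rt.id
       JOIN annotations a ON a.key = rk.key
     WHERE rt.max_x >= ?1 AND rt.min_x <= ?2
       AND rt.max_y >= ?3 AND rt.min_y <= ?4
       AND a.x1 >= ?1 AND a.x0 <= ?2 AND a.y1 >= ?3 AND a.y0 <= ?4",
    params = list(bounds[1], bounds[3], bounds[2], bounds[4]))$key
}

#' Spatial + predicate query
#'
#' Three stages: bounding-box prefilter (R-Tree on the database backend),
#' exact geometric intersection against `geometry`, then the optional
#' property predicate. On the database backend a translatable predicate is
#' evaluated inside SQLite (`json_extract`); untranslatable predicates fall
#' back to interpreted filtering -- both paths return identical sets.
#'
#' @param store an `annotation_store`.
#' @param geometry a `wsi_geometry` to intersect with (or a length-4
#'   numeric treated as a rectangle), or `NULL` for no spatial filter.
#' @param where optional [predicate()] or expression string over `props`.
#' @return named list of matching [annotation()]s.
#' @export
store_query <- function(store, geometry = NULL, where = NULL) {
  pred <- as_predicate(where)
  if (is.numeric(geometry) && length(geometry) == 4) {
    geometry <- geom_polygon(rbind(
      c(geometry[1], geometry[2]), c(geometry[3], geometry[2]),
      c(geometry[3], geometry[4]), c(geometry[1], geometry[4])))
  }
  keys <- if (is.null(geometry)) store_keys(store) else
    bquery(store, geom_bbox(geometry))
  sql_where <- if (!is.null(pred) && inherits(store, "db_store")) {
    predicate_to_sql(pred)
  } else {
    NULL
  }
  if (!is.null(sql_where) && length(keys) > 0) {
    ph <- paste(rep("?", length(keys)), collapse = ",")
    keys <- DBI::dbGetQuery(store$con, sprintf(
      "SELECT key FROM annotations WHERE key IN (%s) AND (%s)", ph,
      sql_where), params = as.list(keys))$key
    pred <- NULL  # already applied in-backend
  }
  out <- list()
  for (k in keys) {
    ann <- store_get(store, k)
    if (!is.null(geometry) && !geoms_intersect(ann$geometry, geometry)) next
    if (!is.null(pred) && !eval_predicate(pred, ann$properties)) next
    out[[k]] <- ann
  }
  out
}

#' Serialize / deserialize one geometry
#'
#' Stand-alone access to the store's geometry codec: WKB, optionally
#' deflate-compressed (zlib, RFC 1950). See [geom_to_wkb()].
#'
#' @param geom a `wsi_geometry`.
#' @param compress deflate the payload.
#' @export
serialize_geometry <- function(geom, compress = FALSE) {
  geom_to_wkb(geom, compress = compress)
}

#' @rdname serialize_geometry
#' @param bytes raw vector from [serialize_geometry()].
#' @export
deserialize_geometry <- function(bytes) geom_from_wkb(bytes)

# --- conversions ------------------------------------------------------------

geom_to_geojson <- function(g) {
  switch(geom_type(g),
    POINT = list(type = "Point", coordinates = as.numeric(g$coords[1, ])),
    LINESTRING = list(type = "LineString",
                      coordinates = unname(split(g$coords,
                                                 seq_len(nrow(g$coords))))),
    POLYGON = list(type = "Polygon",
                   coordinates = list(unname(split(g$coords,
                                                   seq_len(nrow(g$coords)))))))
}

geojson_to_geom <- function(gj) {
  coords_mat <- function(cc) do.call(rbind, lapply(cc, as.numeric))
  switch(gj$type,
    Point = geom_point(gj$coordinates[[1]], gj$coordinates[[2]]),
    LineString = new_geometry("LINESTRING", coords_mat(gj$coordinates)),
    Polygon = new_geometry("POLYGON", coords_mat(gj$coordinates[[1]])),
    abort(sprintf("unsupported GeoJSON geometry '%s'", gj$type),
          "wsikit_parse_error"))
}

feature_of <- function(key, ann) {
  list(type = "Feature", id = key,
       geometry = geom_to_geojson(ann$geometry),
       properties = ann$properties)
}

annotation_from_feature <- function(feat, index = NA) {
  ok <- is.list(feat) && identical(feat$type, "Feature") &&
    is.list(feat$geometry)
  if (!ok) {
    abort(sprintf("malformed GeoJSON feature at index %s", index),
          "wsikit_parse_error")
  }
  props <- feat$properties
  if (is.null(props)) props <- list()
  list(key = if (is.null(feat$id)) NULL else feat$id,
       ann = annotation(geojson_to_geom(feat$geometry), props))
}

#' Convert a store to and from standard formats
#'
#' `store_to_geojson()` / `store_from_geojson()` round-trip an RFC 7946
#' FeatureCollection; `store_to_ndjson()` / `store_from_ndjson()` use
#' line-delimited JSON features (one per annotation);
#' `store_to_table()` flattens scalar top-level properties into data.frame
#' columns; `store_to_mapping()` / `store_from_mapping()` use a plain named
#' list. Geometry round trips are vertex-exact and properties value-exact.
#'
#' @param store an `annotation_store`.
#' @param path file to write, or `NULL` to return the document as a string.
#' @export
store_to_geojson <- function(store, path = NULL) {
  keys <- sort(store_keys(store))
  fc <- list(type = "FeatureCollection",
             features = lapply(keys, function(k)
               feature_of(k, store_get(store, k))))
  doc <- jsonlite::toJSON(fc, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(as.character(doc))
  writeLines(doc, path)
  invisible(path)
}

#' @rdname store_to_geojson
#' @param doc GeoJSON text (used when `path` is `NULL`).
#' @param store_out destination store; a fresh memory store by default.
#' @export
store_from_geojson <- function(doc = NULL, path = NULL,
                               store_out = open_store("memory")) {
  txt <- if (!is.null(path)) paste(readLines(path, warn = FALSE),
                                   collapse = "\n") else doc
  fc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                 error = function(e)
                   abort(sprintf("GeoJSON parse error: %s",
                                 conditionMessage(e)),
                         "wsikit_parse_error"))
  assert_that(identical(fc$type, "FeatureCollection"),
              "not a GeoJSON FeatureCollection", "wsikit_parse_error")
  for (i in seq_along(fc$features)) {
    fa <- annotation_from_feature(fc$features[[i]], index = i)
    store_insert(store_out, fa$ann, key = fa$key)
  }
  store_out
}

#' @rdname store_to_geojson
#' @export
store_to_ndjson <- function(store, path = NULL) {
  keys <- sort(store_keys(store))
  lines <- vapply(keys, function(k) {
    as.character(jsonlite::toJSON(feature_of(k, store_get(store, k)),
                                  digits = I(17), auto_unbox = TRUE))
  }, character(1))
  if (is.null(path)) return(unname(lines))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname store_to_geojson
#' @param lines ndjson lines (used when `path` is `NULL`).
#' @export
store_from_ndjson <- function(lines = NULL, path = NULL,
                              store_out = open_store("memory")) {
  if (!is.null(path)) lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    feat <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                     error = function(e)
                       abort(sprintf("ndjson parse error at line %d: %s", i,
                                     conditionMessage(e)),
                             "wsikit_parse_error"))
    fa <- annotation_from_feature(feat, index = i)
    store_insert(store_out, fa$ann, key = fa$key)
  }
  store_out
}

#' @rdname store_to_geojson
#' @export
store_to_table <- function(store) {
  keys <- sort(store_keys(store))
  anns <- lapply(keys, function(k) store_get(store, k))
  prop_names <- unique(unlist(lapply(anns, function(a) names(a$properties))))
  base <- data.frame(
    key = keys,
    geom_type = vapply(anns, function(a) geom_type(a$geometry), character(1)),
    n_vertices = vapply(anns, function(a) nrow(a$geometry$coords), integer(1)),
    stringsAsFactors = FALSE
  )
  for (p in prop_names) {
    vals <- lapply(anns, function(a) a$properties[[p]])
    scalar <- all(vapply(vals, function(v)
      is.null(v) || (is.atomic(v) && length(v) == 1), logical(1)))
    base[[p]] <- if (scalar) {
      unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
    } else {
      vapply(vals, function(v)
        as.character(jsonlite::toJSON(v, digits = I(17), auto_unbox = TRUE)),
        character(1))
    }
  }
  base
}

#' @rdname store_to_geojson
#' @export
store_to_mapping <- function(store) {
  keys <- sort(store_keys(store))
  stats::setNames(lapply(keys, function(k) store_get(store, k)), keys)
}

#' @rdname store_to_geojson
#' @param mapping named list of annotations.
#' @export
store_from_mapping <- function(mapping, store_out = open_store("memory")) {
  for (k in names(mapping)) {
    store_insert(store_out, as_annotation(mapping[[k]]), key = k)
  }
  store_out
}
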