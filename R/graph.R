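# WSI graph construction: hybrid location+feature agglomerative clustering
# of patches into tissue-region nodes, Delaunay (or k-NN) edges between node
# centroids, and a lossless JSON document round trip. Downstream graph
# learning is out of scope; this module produces the graph itself.

#' Patch feature set
#'
#' @param coords n x 2 matrix of patch centroids (baseline px).
#' @param features n x d matrix of node-level feature vectors.
#' @return a `patch_feature_set`.
#' @export
patch_feature_set <- function(coords, features) {
  coords <- as.matrix(coords); features <- as.matrix(features)
  assert_that(ncol(coords) == 2 && all(is.finite(coords)),
              "coords must be a finite n x 2 matrix")
  assert_that(nrow(features) == nrow(coords) && all(is.finite(features)),
              "features must have one finite row per patch")
  structure(list(coords = coords, features = features),
            class = "patch_feature_set")
}

#' Hybrid location + feature clustering
#'
#' Groups patches by average-linkage agglomerative clustering under the
#' blended distance
#' `D(i,j) = lambda * d_xy(i,j) / s_xy + (1 - lambda) * d_feat(i,j) / s_feat`,
#' where each term is scaled by its population median so the two spaces are
#' unit-free, cut at `dist_threshold`. `lambda = 1` clusters purely by
#' location, `lambda = 0` purely by features.
#'
#' @param pfs a [patch_feature_set()].
#' @param lambda_spatial spatial weight in `[0, 1]`.
#' @param dist_threshold tree cut height; `NULL` uses half the median
#'   blended distance.
#' @return integer cluster membership, one label per patch.
#' @export
hybrid_cluster <- function(pfs, lambda_spatial = 0.5, dist_threshold = NULL) {
  assert_that(inherits(pfs, "patch_feature_set"), "pfs must be a patch_feature_set")
  assert_that(is_scalar_number(lambda_spatial) &&
                lambda_spatial >= 0 && lambda_spatial <= 1,
              "lambda_spatial must be in [0, 1]")
  n <- nrow(pfs$coords)
  if (n == 1) return(1L)
  d_xy <- stats::dist(pfs$coords)
  d_ft <- stats::dist(pfs$features)
  s_xy <- stats::median(d_xy); if (s_xy == 0) s_xy <- 1
  s_ft <- stats::median(d_ft); if (s_ft == 0) s_ft <- 1
  D <- lambda_spatial * d_xy / s_xy + (1 - lambda_spatial) * d_ft / s_ft
  if (is.null(dist_threshold)) dist_threshold <- stats::median(D) / 2
  hc <- stats::hclust(D, method = "average")
  stats::cutree(hc, h = dist_threshold)
}

#' Build a spatial graph from clustered patches
#'
#' Node centroids and features are the means over member patches; edges
#' connect nodes by Delaunay triangulation of the centroids pruned at a
#' centroid-distance threshold (default 4x the median neighbour distance),
#' or by symmetric k-nearest-neighbours. With fewer than three nodes (or
#' degenerate geometry) the Delaunay rule falls back to full linkage under
#' the same distance prune.
#'
#' @param pfs a [patch_feature_set()].
#' @param membership cluster labels from [hybrid_cluster()].
#' @param edge_rule `"delaunay"` or `"knn"`.
#' @param prune_dist drop edges between centroids farther than this
#'   (baseline px); `NULL` for the default above.
#' @param k neighbours for the knn rule.
#' @return a `spatial_graph`: `node_coords` (k x 2), `node_features`
#'   (k x d), `edges` (m x 2, undirected, no self loops), `membership`.
#' @export
build_graph <- function(pfs, membership, edge_rule = c("delaunay", "knn"),
                        prune_dist = NULL, k = 4L) {
  edge_rule <- match.arg(edge_rule)
  assert_that(length(membership) == nrow(pfs$coords),
              "membership length must match patch count")
  labels <- sort(unique(membership))
  k_nodes <- length(labels)
  node_coords <- matrix(0, k_nodes, 2)
  node_features <- matrix(0, k_nodes, ncol(pfs$features))
  for (i in seq_along(labels)) {
    sel <- membership == labels[i]
    node_coords[i, ] <- colMeans(pfs$coords[sel, , drop = FALSE])
    node_features[i, ] <- colMeans(pfs$features[sel, , drop = FALSE])
  }
  edges <- if (k_nodes < 2) {
    matrix(integer(0), 0, 2)
  } else if (edge_rule == "knn") {
    knn_edges(node_coords, k)
  } else {
    delaunay_edges(node_coords)
  }
  if (nrow(edges) > 0) {
    dd <- sqrt(rowSums((node_coords[edges[, 1], , drop = FALSE] -
                          node_coords[edges[, 2], , drop = FALSE])^2))
    if (is.null(prune_dist)) {
      prune_dist <- 4 * stats::median(dd)
    }
    edges <- edges[dd <= prune_dist, , drop = FALSE]
  }
  structure(list(node_coords = node_coords, node_features = node_features,
                 edges = edges,
                 membership = match(membership, labels)),
            class = "spatial_graph")
}

delaunay_edges <- function(coords) {
  n <- nrow(coords)
  if (n < 3 || nrow(unique(coords)) < 3) return(all_pairs_edges(n))
  tri <- tryCatch(
    suppressMessages(deldir::deldir(coords[, 1], coords[, 2],
                                    suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(tri)) return(all_pairs_edges(n))
  e <- as.matrix(tri$delsgs[, c("ind1", "ind2")])
  e <- t(apply(e, 1, sort))
  unique(e)
}

all_pairs_edges <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  e <- t(utils::combn(n, 2))
  storage.mode(e) <- "integer"
  e
}

knn_edges <- function(coords, k) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(min(k, n - 1L))]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(edges)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph %d node(s), %d edge(s), %d feature dim(s)>\n",
              nrow(x$node_coords), nrow(x$edges), ncol(x$node_features)))
  invisible(x)
}

#' Graph document round trip
#'
#' Serializes a `spatial_graph` to JSON (nodes, features, edges,
#' membership) with full floating-point precision, and parses it back
#' losslessly.
#'
#' @param graph a `spatial_graph`.
#' @param path optional file to write; string returned when `NULL`.
#' @export
graph_to_json <- function(graph, path = NULL) {
  doc <- jsonlite::toJSON(list(
    node_coords = graph$node_coords,
    node_features = graph$node_features,
    edges = graph$edges,
    membership = graph$membership
  ), digits = I(17))
  if (is.null(path)) return(as.character(doc))
  writeLines(doc, path)
  invisible(path)
}

#' @rdname graph_to_json
#' @param doc JSON text (used when `path` is `NULL`).
#' @export
graph_from_json <- function(doc = NULL, path = NULL) {
  txt <- if (!is.null(path)) paste(readLines(path, warn = FALSE),
                                   collapse = "\n") else doc
  obj <- tryCatch(jsonlite::fromJSON(txt),
                  error = function(e)
                    abort(sprintf("graph document parse error: %s",
                                  conditionMessage(e)),
                          "wsikit_parse_error"))
  for (fld in c("node_coords", "node_features", "edges", "membership")) {
    assert_that(!is.null(obj[[fld]]),
                sprintf("graph document missing '%s'", fld),
                "wsikit_parse_error")
  }
  edges <- if (length(obj$edges) == 0) matrix(integer(0), 0, 2) else
    matrix(as.integer(as.matrix(obj$edges)), ncol = 2)
  structure(list(node_coords = as.matrix(obj$node_coords),
                 node_features = as.matrix(obj$node_features),
                 edges = edges,
                 membership = as.integer(obj$membership)),
            class = "spatial_graph")
}

#' Project node features to RGB colours
#'
#' Maps node features to colours for overlay rendering by projecting onto
#' the top three principal components, each rescaled to 0..255. The
#' projection is pluggable: pass any `function(features) -> n x 3` matrix.
#'
#' @param graph a `spatial_graph`.
#' @param projection optional custom projection function.
#' @return n x 3 matrix of RGB values in 0..255.
#' @export
node_colors <- function(graph, projection = NULL) {
  f <- graph$node_features
  if (!is.null(projection)) {
    rgb <- projection(f)
  } else {
    ctr <- scale(f, center = TRUE, scale = FALSE)
    k <- min(3, ncol(f), nrow(f))
    pc <- if (nrow(f) > 1) stats::prcomp(ctr)$x[, seq_len(k), drop = FALSE]
          else matrix(0, nrow(f), k)
    rgb <- matrix(128, nrow(f), 3)
    for (j in seq_len(k)) {
      rng <- range(pc[, j])
      rgb[, j] <- if (diff(rng) > 0) {
        255 * (pc[, j] - rng[1]) / diff(rng)
      } else {
        128
      }
    }
  }
  clamp(round(rgb), 0, 255)
}
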