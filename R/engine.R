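# Model-agnostic inference engine: batched patch prediction, whole-slide
# patch classification with record serialization and map merging, tiled
# per-pixel segmentation with overlap averaging, feature extraction, a
# generic tile-level instance merging contract, and slide-level pooling.

#' Batched patch inference
#'
#' Runs `model$infer_batch` over `images` in batches, applying the model's
#' `postprocess` per output. Results are independent of `batch_size`.
#'
#' @param model a [model_contract()].
#' @param images list of image arrays matching `model$input_size`.
#' @param batch_size images per inference call.
#' @return list of model outputs, one per image, order preserved.
#' @export
predict_patches <- function(model, images, batch_size = 32L) {
  assert_that(inherits(model, "model_contract"), "model must satisfy the contract")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  if (!is.null(model$input_size)) {
    for (img in images) {
      d <- dim(as_image_array(img))
      assert_that(d[2] == model$input_size[1] && d[1] == model$input_size[2],
                  sprintf("patch is %dx%d but the model expects %dx%d",
                          d[2], d[1], model$input_size[1],
                          model$input_size[2]))
    }
  }
  n <- length(images)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    batch_out <- model$infer_batch(images[i:j])
    assert_that(length(batch_out) == j - i + 1L,
                "infer_batch returned a different batch length")
    out[i:j] <- batch_out
    i <- j + 1L
  }
  if (!is.null(model$postprocess)) out <- lapply(out, model$postprocess)
  out
}

label_of <- function(probs) which.max(probs)

#' Whole-slide patch classification
#'
#' Full pipeline: [grid_coordinates()] on the slide, optional
#' [filter_by_mask()], lazy patch iteration, batched inference, and result
#' aggregation. Records (key, bounds, label, probabilities) are serialized
#' as JSON-lines to `out_file`; the merged prediction map places each
#' patch's probabilities at its grid cell -- one map pixel per stride step;
#' overlapping patch footprints (stride < patch) are not blended.
#'
#' @param model patch-label [model_contract()].
#' @param reader slide `wsi_reader`.
#' @param grid a [patch_grid_spec()].
#' @param mask optional mask reader from [make_mask()].
#' @param out_file records path; defaults to a tempfile.
#' @param batch_size inference batch size.
#' @return list with `records` (path), `map` (a `prediction_map`), and the
#'   kept `coords`.
#' @export
predict_wsi <- function(model, reader, grid, mask = NULL, out_file = NULL,
                        batch_size = 32L) {
  assert_that(model$task == "patch_label", "predict_wsi needs a patch_label model")
  if (is.null(out_file)) out_file <- tempfile(fileext = ".jsonl")
  coords <- grid_coordinates(reader$meta, grid)
  n_total <- nrow(coords)
  if (!is.null(mask)) {
    coords <- filter_by_mask(coords, mask, grid$min_mask_ratio)
  }
  g <- baseline_patch_geometry(reader$meta, grid)
  nx <- if (n_total) max(coords_full_grid_n(reader$meta, grid)[1], 1L) else 0L
  ny <- if (n_total) max(coords_full_grid_n(reader$meta, grid)[2], 1L) else 0L
  probs_map <- array(NA_real_, c(ny, nx, model$output_channels))
  label_map <- matrix(NA_integer_, ny, nx)
  con <- file(out_file, "w")
  on.exit(close(con))
  if (nrow(coords) == 0) {
    warning("no patches to process (empty grid after masking)", call. = FALSE)
    return(list(records = out_file,
                map = new_prediction_map(probs_map, label_map, reader$meta,
                                         g$stride),
                coords = coords))
  }
  it <- iter_patches(reader, coords, grid)
  done <- 0L
  while (done < nrow(coords)) {
    take <- min(batch_size, nrow(coords) - done)
    batch <- vector("list", take)
    rows <- integer(take)
    for (b in seq_len(take)) {
      nxt <- it()
      batch[[b]] <- nxt$image
      rows[b] <- done + b
    }
    outs <- predict_patches(model, batch, batch_size = batch_size)
    for (b in seq_len(take)) {
      row <- coords[rows[b], ]
      probs <- as.numeric(outs[[b]])
      lab <- label_of(probs)
      if (!is.na(row$j)) {
        probs_map[row$j + 1L, row$i + 1L, ] <- probs
        label_map[row$j + 1L, row$i + 1L] <- lab
      }
      writeLines(jsonlite::toJSON(list(
        key = row$key, bounds = c(row$x0, row$y0, row$x1, row$y1),
        label = lab, probabilities = probs
      ), digits = I(17), auto_unbox = TRUE), con)
    }
    done <- done + take
  }
  list(records = out_file,
       map = new_prediction_map(probs_map, label_map, reader$meta, g$stride),
       coords = coords)
}

coords_full_grid_n <- function(meta, spec) {
  g <- baseline_patch_geometry(meta, spec)
  sd <- meta$slide_dimensions
  n_axis <- function(L, p, s) {
    if (spec$edge_policy == "discard_partial") {
      if (L < p) 0L else floor((L - p) / s) + 1L
    } else {
      ceiling(L / s)
    }
  }
  c(n_axis(sd[1], g$patch[1], g$stride[1]),
    n_axis(sd[2], g$patch[2], g$stride[2]))
}

#' Prediction map
#'
#' A raster of model outputs registered to slide coordinates: `probs` is
#' `(rows, cols, channels)`, `labels` the per-cell argmax, `cell_size` the
#' baseline extent of one map pixel. `as_virtual()`-compatible via
#' [prediction_map_reader()].
#'
#' @name prediction_map
NULL

new_prediction_map <- function(probs, labels, donor_meta, cell_size) {
  structure(list(probs = probs, labels = labels, donor_meta = donor_meta,
                 cell_size = cell_size),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map %d x %d cells, %d channel(s)>\n",
              ncol(x$labels), nrow(x$labels), dim(x$probs)[3]))
  invisible(x)
}

#' Wrap a prediction map as a virtual label reader
#' @param map a `prediction_map`.
#' @return virtual `wsi_reader` over the label raster.
#' @export
prediction_map_reader <- function(map) {
  labels <- map$labels
  labels[is.na(labels)] <- 0L
  # pad to the donor aspect so virtual wrapping stays aligned
  as_virtual(labels, map$donor_meta, interpretation = "label")
}

#' Tiled per-pixel inference
#'
#' Splits the requested region (default: whole slide) into tiles at the
#' output resolution, runs the per-pixel model on each tile, and averages
#' probability contributions where tiles overlap, ignoring the model's
#' `NA` margin pixels; the class map is the post-averaging argmax. With
#' `overlap_px >= 2 * model$margin` every interior pixel receives at least
#' one full-receptive-field contribution, making tiled inference equal
#' whole-image inference on interiors for translation-equivariant models.
#'
#' @param model per-pixel [model_contract()].
#' @param reader slide `wsi_reader`.
#' @param tile_size tile side at output resolution.
#' @param overlap_px tile overlap at output resolution.
#' @param output_res output-map resolution.
#' @return a `prediction_map` whose `probs` raster covers the slide at
#'   `output_res`.
#' @export
segment_wsi <- function(model, reader, tile_size = 256L, overlap_px = 16L,
                        output_res = resolution(1, "baseline")) {
  assert_that(model$task == "per_pixel", "segment_wsi needs a per_pixel model")
  assert_that(overlap_px >= 0, "overlap_px must be >= 0")
  assert_that(tile_size > overlap_px, "tile must be larger than the overlap")
  if (overlap_px < 2L * model$margin) {
    warning("overlap smaller than twice the model margin; ",
            "some pixels may lose coverage", call. = FALSE)
  }
  output_res <- as_resolution(output_res)
  scale <- relative_scale(reader$meta, output_res)
  sd <- reader$meta$slide_dimensions
  out_w <- max(1L, round(sd[1] * scale[1]))
  out_h <- max(1L, round(sd[2] * scale[2]))
  ch <- model$output_channels
  acc <- array(0, c(out_h, out_w, ch))
  cnt <- array(0, c(out_h, out_w, ch))
  step <- tile_size - overlap_px
  x_starts <- unique(pmin(seq(0L, max(out_w - 1L, 0L), by = step),
                          max(out_w - tile_size, 0L)))
  y_starts <- unique(pmin(seq(0L, max(out_h - 1L, 0L), by = step),
                          max(out_h - tile_size, 0L)))
  for (ty in y_starts) for (tx in x_starts) {
    tw <- min(tile_size, out_w - tx)
    th <- min(tile_size, out_h - ty)
    bounds <- c(tx / scale[1], ty / scale[2],
                (tx + tw) / scale[1], (ty + th) / scale[2])
    tile <- read_region_core(reader, bounds, c(tw, th), scale)
    raw <- model$infer_batch(list(tile))[[1]]
    if (!is.null(model$postprocess)) raw <- model$postprocess(raw)
    raw <- as_image_array(raw)
    ok <- !is.na(raw)
    ys <- (ty + 1L):(ty + th)
    xs <- (tx + 1L):(tx + tw)
    acc_blk <- acc[ys, xs, , drop = FALSE]
    cnt_blk <- cnt[ys, xs, , drop = FALSE]
    acc_blk[ok] <- acc_blk[ok] + raw[ok]
    cnt_blk[ok] <- cnt_blk[ok] + 1
    acc[ys, xs, ] <- acc_blk
    cnt[ys, xs, ] <- cnt_blk
  }
  probs <- acc / ifelse(cnt > 0, cnt, NA)
  labels <- matrix(NA_integer_, out_h, out_w)
  covered <- cnt[, , 1] > 0
  if (ch > 1) {
    flat <- matrix(probs, ncol = ch)
    labels[covered] <- max.col(flat[as.vector(covered), , drop = FALSE],
                               ties.method = "first")
  } else {
    labels[covered] <- 1L
  }
  new_prediction_map(probs, labels, reader$meta, 1 / scale)
}

#' Per-patch feature extraction
#'
#' Runs a feature model over the (optionally mask-filtered) grid and
#' returns one fixed-length vector per kept patch.
#'
#' @inheritParams predict_wsi
#' @return data.frame: `key`, bounds columns, and `f1..fk` feature columns.
#' @export
extract_features <- function(model, reader, grid, mask = NULL,
                             batch_size = 32L) {
  assert_that(model$task == "feature", "extract_features needs a feature model")
  coords <- grid_coordinates(reader$meta, grid)
  if (!is.null(mask)) coords <- filter_by_mask(coords, mask, grid$min_mask_ratio)
  if (nrow(coords) == 0) {
    return(cbind(coords,
                 matrix(numeric(0), 0, model$output_channels,
                        dimnames = list(NULL,
                                        paste0("f", seq_len(model$output_channels))))))
  }
  imgs <- collect_patches(reader, coords, grid)
  feats <- predict_patches(model, imgs, batch_size = batch_size)
  fm <- do.call(rbind, lapply(feats, as.numeric))
  colnames(fm) <- paste0("f", seq_len(ncol(fm)))
  cbind(coords, as.data.frame(fm))
}

#' Merge tile-level instances into the slide frame
#'
#' Implements the generic overlapping-tile instance-merging contract:
#' instances touching a tile's inner boundary (a tile edge that is not also
#' a slide edge) are dropped -- with sufficient overlap each such instance
#' lies fully inside a neighbouring tile -- survivors are shifted into the
#' slide frame, and duplicates (centroids within `tol` pixels) are removed.
#'
#' @param tile_results list of `list(bounds = c(x0, y0, x1, y1), instances =
#'   list)`; each instance has a tile-local `centroid` and optionally a
#'   `boundary` polygon matrix and arbitrary extra fields.
#' @param tile_overlap overlap used when tiling, baseline px.
#' @param slide_dims slide `(width, height)`; tile edges on the slide
#'   boundary are not "inner".
#' @param tol centroid deduplication tolerance, px.
#' @return list of instances with slide-frame coordinates.
#' @export
merge_instances <- function(tile_results, tile_overlap, slide_dims,
                            tol = 1) {
  if (tile_overlap == 0) {
    touching <- any(vapply(tile_results, function(tr) {
      any(vapply(tr$instances, function(inst)
        instance_touches_inner(inst, tr$bounds, slide_dims), logical(1)))
    }, logical(1)))
    if (touching) {
      warning("tile_overlap is 0 and instances touch tile boundaries; ",
              "they are dropped and may be lost", call. = FALSE)
    }
  }
  kept <- list()
  centroids <- matrix(numeric(0), 0, 2)
  for (tr in tile_results) {
    for (inst in tr$instances) {
      if (instance_touches_inner(inst, tr$bounds, slide_dims)) next
      shifted <- inst
      shifted$centroid <- inst$centroid + tr$bounds[1:2]
      if (!is.null(inst$boundary)) {
        shifted$boundary <- sweep(inst$boundary, 2, tr$bounds[1:2], `+`)
      }
      if (nrow(centroids) > 0) {
        dd <- sqrt((centroids[, 1] - shifted$centroid[1])^2 +
                     (centroids[, 2] - shifted$centroid[2])^2)
        if (any(dd <= tol)) next
      }
      kept[[length(kept) + 1L]] <- shifted
      centroids <- rbind(centroids, shifted$centroid)
    }
  }
  kept
}

instance_touches_inner <- function(inst, tile_bounds, slide_dims) {
  bb <- if (!is.null(inst$boundary)) {
    b <- inst$boundary
    c(min(b[, 1]), min(b[, 2]), max(b[, 1]), max(b[, 2]))
  } else {
    c(inst$centroid, inst$centroid)
  }
  tw <- tile_bounds[3] - tile_bounds[1]
  th <- tile_bounds[4] - tile_bounds[2]
  inner_left <- tile_bounds[1] > 0
  inner_top <- tile_bounds[2] > 0
  inner_right <- tile_bounds[3] < slide_dims[1]
  inner_bottom <- tile_bounds[4] < slide_dims[2]
  (inner_left && bb[1] <= 0) || (inner_top && bb[2] <= 0) ||
    (inner_right && bb[3] >= tw) || (inner_bottom && bb[4] >= th)
}

#' Slide-level pooling of patch records
#'
#' Pools the chosen class probability over all patch records with the
#' `"max"` or `"mean"` rule (multiple-instance-learning style slide score).
#'
#' @param records path to a JSON-lines record file from [predict_wsi()], or
#'   a list of record objects.
#' @param rule pooling rule.
#' @param class_index 1-based class whose probability is pooled.
#' @return scalar slide score.
#' @export
pool_slide <- function(records, rule = c("max", "mean"), class_index = 2L) {
  rule <- match.arg(rule)
  recs <- read_records(records)
  assert_that(length(recs) >= 1, "no records to pool")
  p <- vapply(recs, function(r) r$probabilities[class_index], numeric(1))
  if (rule == "max") max(p) else mean(p)
}

#' Read a JSON-lines record file
#' @param records path or already-parsed list.
#' @return list of record objects.
#' @export
read_records <- function(records) {
  if (is.character(records)) {
    lines <- readLines(records)
    lapply(lines, function(l) jsonlite::fromJSON(l))
  } else {
    records
  }
}
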