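# Inference engine: batching, whole-slide aggregation, tiled segmentation,
# features, instance merging, pooling.

test_that("predict_patches is batched, ordered and shape-checked", {
  const <- model_contract("patch_label", output_channels = 2,
                          infer_batch = function(b)
                            lapply(b, function(x) c(0.3, 0.7)))
  imgs <- lapply(1:7, function(i) array(i, c(8, 8, 3)))
  out <- predict_patches(const, imgs, batch_size = 3)
  expect_length(out, 7)
  expect_true(all(vapply(out, function(p) which.max(p) == 2, logical(1))))

  # mean-intensity labels equal the unbatched per-image oracle
  model <- model_mean_intensity(threshold = 128)
  set.seed(2)
  patches <- lapply(1:10, function(i)
    array(runif(192) * 255, c(8, 8, 3)))
  got <- vapply(predict_patches(model, patches),
                which.max, integer(1))
  want <- vapply(patches, function(p)
    if (mean(p) < 128) 2L else 1L, integer(1))
  expect_identical(got, want)

  # declared input size enforced
  sized <- model_mean_intensity(input_size = c(16, 16))
  expect_error(predict_patches(sized, list(array(0, c(8, 8, 3)))),
               class = "wsikit_validation_error")
})

test_that("batch size never changes results", {
  model <- model_mean_intensity()
  set.seed(3)
  imgs <- lapply(1:33, function(i) array(runif(48) * 255, c(4, 4, 3)))
  expect_identical(predict_patches(model, imgs, batch_size = 1),
                   predict_patches(model, imgs, batch_size = 32))
})

test_that("predict_wsi merges patch results onto the slide grid", {
  fx <- fixture_slide()
  model <- model_mean_intensity(threshold = 220)
  grid <- patch_grid_spec(c(128, 128))
  mask <- make_mask(fx$reader, res = resolution(16, "mpp"))
  res <- predict_wsi(model, fx$reader, grid, mask = mask)

  recs <- read_records(res$records)
  expect_length(recs, nrow(res$coords))
  for (r in recs[1:3]) {
    expect_true(abs(sum(r$probabilities) - 1) < 1e-6)
  }

  # map values equal direct model calls placed by an independent oracle
  it <- iter_patches(fx$reader, res$coords, grid)
  repeat {
    p <- it()
    if (is.null(p)) break
    want <- model$infer_batch(list(p$image))[[1]]
    got <- res$map$probs[p$coord$j + 1, p$coord$i + 1, ]
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }

  # tissue blob recovered in the label map at map resolution
  lab <- res$map$labels
  tissue_cells <- !is.na(lab) & lab == 2
  gtm <- wsikit:::rasterize_polygons(
    fx$ground_truth$tissue_polygons, ncol(lab), nrow(lab),
    scale = c(ncol(lab) / 1024, nrow(lab) / 768))
  iou <- sum(tissue_cells & gtm) / sum(tissue_cells | gtm)
  expect_gte(iou, 0.6)

  # all-background mask -> zero records + warning
  none <- as_virtual(matrix(0, 96, 128), fx$reader$meta, "label")
  expect_warning(empty <- predict_wsi(model, fx$reader, grid, mask = none),
                 "no patches")
  expect_length(readLines(empty$records), 0)
})

test_that("record files are byte-identical across reruns", {
  fx <- fixture_slide()
  model <- model_mean_intensity(threshold = 220)
  grid <- patch_grid_spec(c(256, 256))
  f1 <- tempfile(); f2 <- tempfile()
  predict_wsi(model, fx$reader, grid, out_file = f1)
  predict_wsi(model, fx$reader, grid, out_file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("tiled per-pixel inference equals whole-image inference inside", {
  fx <- fixture_slide()
  model <- model_mean_filter(3)
  seg <- segment_wsi(model, fx$reader, tile_size = 200, overlap_px = 16,
                     output_res = resolution(0.5, "baseline"))
  whole <- read_bounds(fx$reader, c(0, 0, 1024, 768),
                       resolution(0.5, "baseline"))
  want <- model$infer_batch(list(whole))[[1]]
  ii <- 2:(nrow(want) - 1); jj <- 2:(ncol(want) - 1)
  expect_lt(max(abs(seg$probs[ii, jj, ] - want[ii, jj, ])), 1e-6)

  # identity model reproduces the resized input
  ident <- model_contract("per_pixel", output_channels = 3,
                          infer_batch = function(b) b)
  seg2 <- segment_wsi(ident, fx$reader, tile_size = 256, overlap_px = 0,
                      output_res = resolution(0.25, "baseline"))
  resized <- read_bounds(fx$reader, c(0, 0, 1024, 768),
                         resolution(0.25, "baseline"))
  expect_lt(max(abs(seg2$probs - resized)), 1e-9)

  expect_error(segment_wsi(ident, fx$reader, tile_size = 8, overlap_px = 8),
               class = "wsikit_validation_error")
})

test_that("per-pixel maps localize a known half-plane boundary", {
  img <- array(200, c(120, 160, 3))
  img[, 81:160, ] <- 40
  r <- open_reader(img)
  twoclass <- model_contract(
    "per_pixel", output_channels = 2, margin = 0,
    infer_batch = function(b) lapply(b, function(x) {
      p_dark <- clamp(1 - x[, , 1] / 255, 0, 1)
      array(c(1 - p_dark, p_dark), c(dim(x)[1], dim(x)[2], 2))
    }))
  seg <- segment_wsi(twoclass, r, tile_size = 64, overlap_px = 8)
  boundary_cols <- apply(seg$labels, 1, function(row)
    which(row == 2)[1])
  expect_true(all(abs(boundary_cols - 81) <= 2))
})

test_that("feature extraction matches the per-patch histogram oracle", {
  gray <- open_reader(array(100, c(64, 64, 3)))
  model <- model_histogram(8)
  grid <- patch_grid_spec(c(32, 32))
  ft <- extract_features(model, gray, grid)
  expect_equal(nrow(ft), 4)
  fcols <- grep("^f", names(ft))
  expect_length(fcols, 24)
  # uniform gray: all mass in bin floor(100/32)+1 = 4 per channel
  expect_true(all(ft[, fcols[c(4, 12, 20)]] == 1))
  expect_true(all(rowSums(ft[, fcols]) == 3))

  fx <- fixture_slide()
  grid2 <- patch_grid_spec(c(128, 128))
  ft2 <- extract_features(model, fx$reader, grid2)
  coords <- grid_coordinates(fx$reader$meta, grid2)
  expect_equal(nrow(ft2), nrow(coords))
  k <- 17
  img <- read_rect(fx$reader, c(coords$x0[k], coords$y0[k]), c(128, 128))
  want <- unlist(lapply(1:3, function(ch) {
    tabulate(pmin(floor(img[, , ch] / 32), 7) + 1, nbins = 8) / (128 * 128)
  }))
  expect_equal(as.numeric(ft2[k, fcols]), want, tolerance = 1e-12)
})

test_that("instance merging drops inner-boundary hits and deduplicates", {
  slide <- c(1000, 800)
  disk <- function(cx, cy, r = 10) {
    t <- seq(0, 2 * pi, length.out = 17)[-17]
    list(centroid = c(cx, cy),
         boundary = cbind(cx + r * cos(t), cy + r * sin(t)))
  }
  tiles <- list(
    list(bounds = c(0, 0, 520, 800),
         instances = list(disk(100, 100), disk(510, 400))),
    list(bounds = c(480, 0, 1000, 800),
         instances = list(disk(30, 400), disk(400, 600)))
  )
  merged <- merge_instances(tiles, tile_overlap = 40, slide_dims = slide)
  cents <- t(vapply(merged, function(m) m$centroid, numeric(2)))
  expect_equal(nrow(cents), 3)
  expect_true(any(abs(cents[, 1] - 510) < 1e-9))  # seam disk kept once

  expect_length(merge_instances(list(list(bounds = c(0, 0, 500, 500),
                                          instances = list())),
                                40, slide), 0)

  expect_warning(
    merge_instances(list(list(bounds = c(0, 0, 520, 800),
                              instances = list(disk(515, 100)))),
                    tile_overlap = 0, slide_dims = slide),
    "dropped")
})

test_that("slide pooling matches its closed forms", {
  recs <- list(list(probabilities = c(0.8, 0.2)),
               list(probabilities = c(0.1, 0.9)),
               list(probabilities = c(0.6, 0.4)))
  expect_equal(pool_slide(recs, "max"), 0.9)
  expect_equal(pool_slide(recs, "mean"), 0.5)
  expect_error(pool_slide(list(), "max"), class = "wsikit_validation_error")

  set.seed(8)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    ps <- lapply(seq_len(n), function(j) {
      p <- runif(3); list(probabilities = p / sum(p))
    })
    idx <- sample(1:3, 1)
    vals <- vapply(ps, function(r) r$probabilities[idx], numeric(1))
    expect_equal(pool_slide(ps, "max", idx), max(vals))
    expect_equal(pool_slide(ps, "mean", idx), mean(vals))
  }
})
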