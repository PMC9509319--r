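# Unified reader: metadata, unit conversion, level planning, the two read
# modes, thumbnails and virtual pyramids.

test_that("fixture metadata round-trips exactly through the file", {
  fx <- fixture_slide()
  meta <- fx$reader$meta
  expect_equal(meta$level_count, 3)
  expect_equal(meta$slide_dimensions, c(1024, 768))
  expect_equal(meta$mpp, c(0.5, 0.5))
  expect_equal(meta$objective_power, 40)
  expect_equal(meta$level_downsamples, c(1, 2, 4))
  expect_equal(meta$level_dimensions,
               lapply(fx$ground_truth$level_dimensions, as.numeric))
})

test_that("flat images and arrays open with override metadata", {
  png_path <- file.path(fixture_dir(), "flat.png")
  img <- array(runif(64 * 48 * 3), c(48, 64, 3))
  png::writePNG(img, png_path)
  r <- open_reader(png_path, mpp = 8)
  expect_equal(r$meta$level_count, 1)
  expect_equal(r$meta$level_downsamples, 1.0)
  expect_equal(r$meta$mpp, c(8, 8))

  ra <- open_reader(array(0.5, c(30, 50, 3)))
  expect_equal(ra$meta$slide_dimensions, c(50, 30))

  expect_error(open_reader("/nope/missing.tiff"),
               class = "wsikit_format_error")
  expect_error(open_reader("helper-fixtures.R"),
               class = "wsikit_format_error")
})

test_that("relative_scale converts every unit correctly", {
  meta <- wsi_meta(c(1000, 800), list(c(1000, 800), c(500, 400)),
                   mpp = 0.25, objective_power = 40)
  expect_equal(relative_scale(meta, resolution(20, "power")), c(0.5, 0.5))
  expect_equal(relative_scale(meta, resolution(0.5, "mpp")), c(0.5, 0.5))
  expect_equal(relative_scale(meta, resolution(1, "level")), c(0.5, 0.5))
  expect_equal(relative_scale(meta, resolution(0.3, "baseline")), c(0.3, 0.3))

  bare <- wsi_meta(c(100, 100), list(c(100, 100)))
  expect_error(relative_scale(bare, resolution(0.5, "mpp")),
               class = "wsikit_unit_error")
  expect_error(relative_scale(bare, resolution(20, "power")),
               class = "wsikit_unit_error")
  # raised at read time, not at open time
  r <- open_reader(array(1, c(10, 10, 3)))
  expect_error(read_rect(r, c(0, 0), c(5, 5), resolution(1, "mpp")),
               class = "wsikit_unit_error")
})

test_that("plan_read picks the best stored level and pads out-of-slide", {
  meta <- wsi_meta(c(1024, 768),
                   list(c(1024, 768), c(512, 384), c(256, 192)),
                   mpp = 0.5)
  p <- plan_read(meta, c(0, 0, 400, 400), resolution(0.25, "baseline"))
  expect_equal(p$source_level, 2)
  expect_equal(p$post_scale, c(1, 1))

  p <- plan_read(meta, c(0, 0, 400, 400), resolution(0.3, "baseline"))
  expect_equal(p$source_level, 1)
  expect_equal(p$post_scale, c(0.6, 0.6))

  expect_warning(
    p <- plan_read(meta, c(0, 0, 400, 400), resolution(2, "baseline")),
    "upscal")
  expect_equal(p$source_level, 0)
  expect_equal(p$post_scale, c(2, 2))

  p <- plan_read(meta, c(-100, 0, 100, 100), resolution(1, "baseline"))
  expect_equal(unname(p$pad_spec["left"]), 100)

  expect_error(plan_read(meta, c(10, 10, 10, 20), 1),
               class = "wsikit_validation_error")
})

test_that("read_rect returns exactly the requested size at any resolution", {
  fx <- fixture_slide()
  r <- fx$reader
  for (res in list(resolution(0.5, "mpp"), resolution(1, "mpp"),
                   resolution(2, "mpp"))) {
    img <- read_rect(r, c(100, 100), c(224, 224), res)
    expect_equal(dim(img)[1:2], c(224, 224))
  }
  # randomized shape property over locations/sizes/units
  set.seed(31)
  for (i in 1:60) {
    size <- sample(5:97, 2, replace = TRUE)
    loc <- c(runif(1, -50, 1100), runif(1, -50, 800))
    res <- switch(sample(1:4, 1),
                  resolution(runif(1, 0.3, 1.5), "baseline"),
                  resolution(runif(1, 0.5, 8), "mpp"),
                  resolution(sample(c(10, 20, 40), 1), "power"),
                  resolution(sample(0:2, 1), "level"))
    img <- suppressWarnings(read_rect(r, loc, size, res))
    expect_identical(dim(img)[1:2], as.integer(c(size[2], size[1])))
  }
})

test_that("baseline identity reads are pixel-exact", {
  fx <- fixture_slide()
  full <- read_rect(fx$reader, c(0, 0), c(1024, 768))
  pages <- tiff::readTIFF(fx$path)
  expect_equal(full, pages * 255, ignore_attr = TRUE)
})

test_that("out-of-slide area follows pad_mode exactly", {
  fx <- fixture_slide()
  r <- fx$reader
  img <- read_rect(r, c(-100, -100), c(200, 200), pad_value = 0)
  expect_true(all(img[1:100, 1:100, ] == 0))
  l0 <- read_rect(r, c(0, 0), c(100, 100))
  expect_equal(img[101:200, 101:200, ], l0, ignore_attr = TRUE)

  refl <- read_rect(r, c(-10, 0), c(20, 20), pad_mode = "reflect")
  expect_equal(dim(refl)[1:2], c(20, 20))
  # reflection mirrors without repeating the edge column
  expect_equal(refl[, 10, ], refl[, 12, ], ignore_attr = TRUE)

  expect_error(read_rect(r, c(-10, 0), c(20, 20), pad_mode = "none"),
               class = "wsikit_validation_error")
  expect_error(read_rect(r, c(0, 0), c(0, 5)),
               class = "wsikit_validation_error")
})

test_that("read_bounds has invariant field of view and scaling output size", {
  fx <- fixture_slide()
  r <- fx$reader
  expect_equal(dim(read_bounds(r, c(0, 0, 1000, 1000),
                               resolution(0.5, "baseline")))[1:2],
               c(500, 500))

  rb <- read_bounds(r, c(0, 0, 1000, 760))
  rr <- read_rect(r, c(0, 0), c(1000, 760))
  expect_equal(rb, rr)

  # level read vs downsampled-baseline oracle
  pages <- tiff::readTIFF(fx$path, all = TRUE)
  b <- c(64, 32, 576, 416)
  lvl <- read_bounds(r, b, resolution(1, "level"))
  crop <- (pages[[1]] * 255)[(b[2] + 1):b[4], (b[1] + 1):b[3], ]
  oracle <- resize_image(crop, dim(lvl)[2], dim(lvl)[1], "area")
  expect_lt(mean(abs(lvl - oracle)), 3)
})

test_that("reading at s then downsampling approximates reading at s/k", {
  fx <- fixture_slide()
  r <- fx$reader
  b <- c(0, 0, 512, 512)
  hi <- read_bounds(r, b, resolution(0.5, "baseline"))
  lo <- read_bounds(r, b, resolution(0.25, "baseline"))
  down <- resize_image(hi, 128, 128, "area")
  expect_lt(mean(abs(down - lo)), 3)
})

test_that("thumbnails preserve aspect ratio and honour units", {
  fx <- fixture_slide()
  th <- slide_thumbnail(fx$reader, resolution(32, "mpp"))
  expect_equal(dim(th)[1:2], c(12, 16))

  flat <- open_reader(array(runif(300), c(10, 10, 3)))
  expect_equal(slide_thumbnail(flat, resolution(1, "baseline")),
               flat$levels[[1]], ignore_attr = TRUE)

  for (w in c(333, 515, 1024)) {
    rr <- open_reader(array(0.5, c(200, w, 3)))
    t2 <- slide_thumbnail(rr, resolution(1 / 7, "baseline"))
    aspect <- w / 200
    err <- min(abs(dim(t2)[2] - dim(t2)[1] * aspect),
               abs(dim(t2)[1] - dim(t2)[2] / aspect))
    expect_lte(err, 1)
  }
})

test_that("virtual readers stay registered to the donor slide", {
  fx <- fixture_slide()
  r <- fx$reader
  mask_small <- (slide_thumbnail(r, resolution(1 / 32, "baseline"))[, , 1] <
                   200) * 1
  vr <- as_virtual(mask_small, r$meta, interpretation = "label")
  expect_identical(vr$meta$slide_dimensions, r$meta$slide_dimensions)

  for (b in list(c(0, 0, 512, 512), c(100, 50, 800, 700))) {
    a <- read_bounds(vr, b, resolution(0.25, "baseline"))
    bb <- read_bounds(r, b, resolution(0.25, "baseline"))
    expect_identical(dim(a)[1:2], dim(bb)[1:2])
    expect_true(all(a %in% c(0, 1)))  # nearest neighbour closure
  }

  # label upscaling invents no values
  lab <- matrix(c(0, 1, 1, 0), 2, 2)
  vr2 <- as_virtual(lab, wsi_meta(c(2, 2), list(c(2, 2))), "label")
  up <- read_bounds(vr2, c(0, 0, 2, 2), resolution(4, "baseline"))
  expect_true(all(up %in% c(0, 1)))

  # ground-truth mask wrapped virtually reads back like a direct
  # rasterization at the requested resolution
  gt <- fx$ground_truth
  gm2 <- wsikit:::rasterize_polygons(gt$tissue_polygons, 512, 384,
                                     scale = c(1 / 2, 1 / 2)) * 1
  vgt <- as_virtual(gm2, r$meta, interpretation = "label")
  m <- read_bounds(vgt, c(0, 0, 1024, 768),
                   resolution(1 / 8, "baseline"))[, , 1]
  gtm <- wsikit:::rasterize_polygons(gt$tissue_polygons, 128, 96,
                                     scale = c(1 / 8, 1 / 8))
  iou <- sum(m == 1 & gtm) / sum(m == 1 | gtm)
  expect_gte(iou, 0.99)

  expect_error(as_virtual(matrix(0, 10, 90), r$meta),
               class = "wsikit_validation_error")
})
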