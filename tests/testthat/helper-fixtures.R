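# Shared fixtures, built once per test run and cached. Slides are written
# to a session temp dir; everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dir <- function() {
  d <- file.path(tempdir(), "wsikit-fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# a pyramidal fixture slide; memoised by name
fixture_slide <- function(name = "default",
                          width = 1024, height = 768, n_levels = 3,
                          mpp = 0.5, power = 40, seed = 7) {
  key <- paste0("slide_", name)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- slide_spec(width, height, n_levels = n_levels, mpp = mpp,
                     objective_power = power, seed = seed)
  path <- file.path(fixture_dir(), paste0(name, ".tiff"))
  fx <- make_pyramid_slide(spec, path)
  fx$spec <- spec
  fx$reader <- open_reader(path, objective_power = power)
  .fixture_cache[[key]] <- fx
  fx
}

fixture_he <- function(seed = 1, width = 128, height = 96,
                       gt = stain_ground_truth()) {
  make_he_image(gt, width, height, seed = seed)
}

row_cosine <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(a[i, ] * b[i, ]) / sqrt(sum(a[i, ]^2) * sum(b[i, ]^2))
  }, numeric(1))
}

# independent Otsu oracle: exhaustively minimise the weighted intra-class
# variance over all 255 splits
otsu_oracle <- function(h) {
  v <- 0:255
  best <- Inf
  bt <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:(t + 1)] * v[1:(t + 1)]) / w0
    m1 <- sum(h[(t + 2):256] * v[(t + 2):256]) / w1
    s <- sum(h[1:(t + 1)] * (v[1:(t + 1)] - m0)^2) +
      sum(h[(t + 2):256] * (v[(t + 2):256] - m1)^2)
    if (s < best - 1e-9) { best <- s; bt <- t }
  }
  bt
}

random_histogram <- function() {
  h <- numeric(256)
  n_modes <- sample(1:4, 1)
  for (m in seq_len(n_modes)) {
    mu <- runif(1, 0, 255); sd <- runif(1, 2, 60)
    h <- h + stats::dnorm(0:255, mu, sd) * runif(1, 100, 10000)
  }
  h <- round(h + stats::rpois(256, 0.5))
  if (sum(h > 0) < 2) h[c(40, 200)] <- h[c(40, 200)] + 1
  h
}

# independent grid-count oracle: walk anchors explicitly
grid_count_oracle <- function(L, p, s, policy) {
  n <- 0L
  anchor <- 0
  repeat {
    if (policy == "discard_partial") {
      if (anchor + p > L) break
    } else {
      if (anchor >= L) break
    }
    n <- n + 1L
    anchor <- anchor + s
  }
  n
}

# brute-force bbox query oracle over a bbox matrix (n x 4)
bbox_query_oracle <- function(bboxes, keys, b) {
  hit <- bboxes[, 1] <= b[3] & b[1] <= bboxes[, 3] &
    bboxes[, 2] <= b[4] & b[2] <= bboxes[, 4]
  keys[hit]
}

expect_same_sets <- function(a, b) {
  testthat::expect_setequal(a, b)
}
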