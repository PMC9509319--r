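# Stain separation, normalization, augmentation against exact Beer-Lambert
# ground truth.

test_that("OD conversion matches its closed form and round-trips", {
  img <- array(255, c(4, 4, 3))
  expect_true(all(rgb_to_od(img) == 0))
  expect_equal(rgb_to_od(array(1, c(1, 1, 3)))[1],
               -log10(1 / 255), tolerance = 1e-12)
  # exhaustive 1..255 round trip within one gray level
  x <- array(rep(0:255, 3), c(16, 16, 3))
  back <- od_to_rgb(rgb_to_od(x))
  expect_true(all(abs(back - pmax(x, 1)) <= 1))
})

test_that("Macenko recovers the generating stain vectors", {
  gt <- stain_ground_truth()
  for (s in 1:5) {
    he <- fixture_he(seed = s)
    M <- macenko_matrix(he$image)
    expect_true(all(row_cosine(M, gt$stain_matrix) >= 0.99))
  }

  # invariant to global concentration scaling
  he <- fixture_he(seed = 3, gt = stain_ground_truth(
    max_concentration = c(0.5, 0.4)))
  he2 <- fixture_he(seed = 3, gt = stain_ground_truth(
    max_concentration = c(1.0, 0.8)))
  M1 <- macenko_matrix(he$image)
  M2 <- macenko_matrix(he2$image)
  expect_true(all(row_cosine(M1, M2) >= 0.995))

  # degenerate single-stain image
  he1 <- fixture_he(seed = 2, width = 64, height = 64,
                    gt = stain_ground_truth(max_concentration = c(1, 0)))
  expect_error(macenko_matrix(he1$image), class = "wsikit_stain_error")

  # insufficient tissue
  expect_error(macenko_matrix(array(255, c(64, 64, 3))),
               class = "wsikit_insufficient_tissue_error")
})

test_that("dictionary learning recovers stains, deterministically", {
  gt <- stain_ground_truth()
  for (s in 1:3) {
    he <- fixture_he(seed = s)
    M <- dictionary_matrix(he$image)
    expect_true(all(row_cosine(M, gt$stain_matrix) >= 0.98))
  }
  he <- fixture_he(seed = 1)
  expect_identical(dictionary_matrix(he$image), dictionary_matrix(he$image))

  # stability across small sparsity settings
  M0 <- dictionary_matrix(he$image, sparsity = 0)
  M1 <- dictionary_matrix(he$image, sparsity = 0.002)
  expect_true(all(row_cosine(M0, M1) >= 0.99))

  # agreement with Macenko on clean fixtures
  Mm <- macenko_matrix(he$image)
  Md <- dictionary_matrix(he$image)
  expect_true(all(row_cosine(Mm, Md) >= 0.98))

  # non-convergence surfaces as a convergence error with diagnostics
  expect_error(dictionary_matrix(he$image, max_iter = 1L, tol = 0),
               class = "wsikit_convergence_error")
})

test_that("OLS concentrations reproduce the generating fields", {
  gt <- stain_ground_truth()
  # relative RMSE pooled over a small image collection (the per-image value
  # fluctuates with how many near-saturated dark pixels a seed draws)
  num <- 0; den <- 0
  for (s in 3:6) {
    he <- fixture_he(seed = s)
    C <- stain_concentrations(he$image, gt$stain_matrix)
    ok <- !he$saturated
    num <- num + sum((C[, , 1][ok] - he$concentrations[, , 1][ok])^2 +
                       (C[, , 2][ok] - he$concentrations[, , 2][ok])^2)
    den <- den + sum(he$concentrations[, , 1][ok]^2 +
                       he$concentrations[, , 2][ok]^2)
  }
  expect_lt(sqrt(num / den), 0.01)
  he <- fixture_he(seed = 4)
  C <- stain_concentrations(he$image, gt$stain_matrix)

  # white image -> all zero
  expect_true(all(stain_concentrations(array(255, c(8, 8, 3)),
                                       gt$stain_matrix) == 0))

  # reconstruction round trip
  recon <- od_to_rgb(array(matrix(C, ncol = 2) %*% gt$stain_matrix,
                           dim(he$image)))
  expect_lt(mean(abs(recon - he$image)), 2)

  expect_error(stain_concentrations(he$image, rbind(c(1, 0, 0), c(1, 0, 0))),
               class = "wsikit_validation_error")
})

test_that("normalizers are fixed points on their own target", {
  he <- fixture_he(seed = 11, width = 96, height = 96)

  nr <- stain_fit(stain_normalizer("reinhard"), he$image)
  expect_lt(mean(abs(stain_transform(nr, he$image) - he$image)), 2)

  nm <- stain_fit(stain_normalizer("macenko"), he$image)
  expect_lt(mean(abs(stain_transform(nm, he$image) - he$image)), 3)

  expect_error(stain_transform(stain_normalizer("reinhard"), he$image),
               class = "wsikit_state_error")
})

test_that("normalizing to a common target converges appearance", {
  # same concentrations, different stain matrices
  gt_a <- stain_ground_truth()
  mat_b <- rbind(c(0.55, 0.75, 0.36), c(0.17, 0.95, 0.25))
  gt_b <- stain_ground_truth(stain_matrix = mat_b)
  a <- make_he_image(gt_a, 96, 96, seed = 21)
  b <- make_he_image(gt_b, 96, 96, seed = 21)
  target <- fixture_he(seed = 30, width = 96, height = 96)

  nm <- stain_fit(stain_normalizer("macenko"), target$image)
  na <- stain_transform(nm, a$image)
  nb <- stain_transform(nm, b$image)
  expect_lt(mean(abs(na - nb)), 5)

  # idempotence: normalizing twice changes nothing beyond quantization
  naa <- stain_transform(nm, na)
  expect_lt(mean(abs(naa - na)), 2)
})

test_that("stain augmentation perturbs concentrations as declared", {
  he <- fixture_he(seed = 11, width = 96, height = 96)
  M <- macenko_matrix(he$image)
  C <- matrix(stain_concentrations(he$image, M), ncol = 2)
  recon <- od_to_rgb(array(C %*% M, dim(he$image)))

  # null perturbation equals the stain round trip
  a0 <- stain_augment(he$image, 0, 0, seed = 5)
  expect_lt(mean(abs(a0 - recon)), 2)

  # deterministic under a fixed seed
  expect_identical(stain_augment(he$image, 0.3, 0.2, seed = 9),
                   stain_augment(he$image, 0.3, 0.2, seed = 9))

  # alpha draws stay inside the declared band: re-estimated per-stain
  # concentration ratios across draws fall within [0.7, 1.3]
  p99 <- apply(C, 2, quantile, probs = 0.99)
  for (s in 1:20) {
    au <- stain_augment(he$image, sigma_alpha = 0.3, sigma_beta = 0,
                        seed = s)
    Ca <- matrix(stain_concentrations(au, M), ncol = 2)
    ratio <- apply(Ca, 2, quantile, probs = 0.99) / p99
    expect_true(all(ratio >= 0.68 & ratio <= 1.32))
  }

  # background-only image passes through with a warning
  expect_warning(out <- stain_augment(array(255, c(32, 32, 3)), 0.2, 0.2),
                 "insufficient tissue")
  expect_true(all(out == 255))
})
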