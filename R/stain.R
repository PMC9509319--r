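# Stain separation, normalization and augmentation. The physical model is
# Beer-Lambert: optical density OD = -log10(I/255) decomposes as OD = C M
# with M the 2 x 3 stain matrix (unit rows: Hematoxylin, Eosin) and C >= 0
# the per-pixel concentrations. Stain matrices are estimated with Macenko's
# angle-percentile method or a 2-atom nonnegative sparse dictionary;
# concentrations are estimated by ordinary least squares with negatives
# clipped to zero.

#' RGB / optical density conversion
#'
#' `rgb_to_od()` computes `-log10(max(I, 1) / 255)` channel-wise;
#' `od_to_rgb()` inverts with `255 * 10^(-OD)` clipped to 0..255. The round
#' trip is exact to within one gray level for inputs in 1..255.
#'
#' @param img `(h, w, 3)` array on the 0..255 scale.
#' @param od optical-density array.
#' @return array of the same shape.
#' @export
rgb_to_od <- function(img) {
  img <- as_image_array(img)
  -log10(pmax(img, 1) / 255)
}

#' @rdname rgb_to_od
#' @export
od_to_rgb <- function(od) {
  quantize_8bit(255 * 10^(-od))
}

od_pixel_matrix <- function(img) {
  img <- as_image_array(img)
  matrix(rgb_to_od(img), ncol = dim(img)[3])
}

# order rows Hematoxylin-first: H has the larger blue-channel OD component
# (ties broken by the smaller red component), and fix signs/normalise
finalize_stain_matrix <- function(m) {
  m[m < 0] <- 0
  norms <- sqrt(rowSums(m^2))
  assert_that(all(norms > 1e-9), "degenerate stain vector",
              "wsikit_stain_error")
  m <- m / norms
  if (m[1, 3] < m[2, 3] || (m[1, 3] == m[2, 3] && m[1, 1] > m[2, 1])) {
    m <- m[c(2, 1), , drop = FALSE]
  }
  m
}

#' Macenko stain matrix estimation
#'
#' Projects high-density pixels (OD norm above `od_min`) onto their top two
#' principal directions and takes the stain vectors at the `angle_pct` and
#' `100 - angle_pct` percentiles of the projected angle, unit-normalised and
#' ordered Hematoxylin first.
#'
#' @param img RGB array, 0..255.
#' @param od_min minimum OD norm for a pixel to count as tissue.
#' @param angle_pct robust angle percentile (percent).
#' @return 2 x 3 stain matrix with unit rows.
#' @export
macenko_matrix <- function(img, od_min = 0.15, angle_pct = 1) {
  od <- od_pixel_matrix(img)
  keep <- sqrt(rowSums(od^2)) > od_min
  if (sum(keep) < 100) {
    abort("insufficient tissue: fewer than 100 pixels above od_min",
          "wsikit_insufficient_tissue_error")
  }
  od <- od[keep, , drop = FALSE]
  sv <- svd(od, nu = 0, nv = 3)
  if (sv$d[2] < 0.02 * sv$d[1]) {
    abort("rank-deficient stain structure (single stain?)",
          "wsikit_stain_error")
  }
  V <- sv$v[, 1:2, drop = FALSE]
  # orient the basis so projections land in a consistent half-plane
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  if (sum(V[, 2]) < 0) V[, 2] <- -V[, 2]
  proj <- od %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(angle_pct, 100 - angle_pct) / 100, names = FALSE)
  v1 <- V %*% c(cos(q[1]), sin(q[1]))
  v2 <- V %*% c(cos(q[2]), sin(q[2]))
  finalize_stain_matrix(rbind(as.numeric(v1), as.numeric(v2)))
}

#' Dictionary-learning stain matrix estimation
#'
#' Learns a 2-atom nonnegative dictionary for the high-density OD pixels by
#' exact alternating nonnegative least squares: closed-form two-variable
#' nonnegative lasso for the codes, per-channel NNLS for the atoms, atoms
#' projected onto the unit ball. The L1 penalty must stay well below the
#' per-pixel OD scale, otherwise the optimum trades cone coverage for code
#' mass and drifts inside the stain cone. Deterministic under a fixed seed;
#' converges when the atoms stop moving or the objective stalls.
#'
#' @inheritParams macenko_matrix
#' @param sparsity L1 penalty on the codes.
#' @param seed seed for the pixel subsample and initialisation.
#' @param max_iter maximum alternations.
#' @param tol atom movement tolerance for convergence.
#' @param max_pixels subsample cap on coded pixels.
#' @return 2 x 3 stain matrix with unit rows.
#' @export
dictionary_matrix <- function(img, sparsity = 0.001, seed = 0L,
                              max_iter = 3000L, tol = 5e-5,
                              max_pixels = 5000L) {
  od <- od_pixel_matrix(img)
  keep <- sqrt(rowSums(od^2)) > 0.15
  if (sum(keep) < 100) {
    abort("insufficient tissue: fewer than 100 pixels above od_min",
          "wsikit_insufficient_tissue_error")
  }
  od <- od[keep, , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (nrow(od) > max_pixels) {
    od <- od[sample.int(nrow(od), max_pixels), , drop = FALSE]
  }
  # init atoms from the colour-ratio extremes (top/bottom decile of the
  # blue-to-green OD balance), which separates the two dyes far better than
  # a mean split and keeps the run deterministic
  ratio <- (od[, 3] + 1e-8) / (od[, 2] + 1e-8)
  qs <- stats::quantile(ratio, c(0.1, 0.9), names = FALSE)
  if (qs[1] == qs[2]) {
    abort("rank-deficient stain structure (single stain?)",
          "wsikit_stain_error")
  }
  D <- rbind(colMeans(od[ratio >= qs[2], , drop = FALSE]),
             colMeans(od[ratio <= qs[1], , drop = FALSE]))
  D <- D / sqrt(rowSums(D^2))
  converged <- FALSE
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    C <- nnls2_codes(od, D, sparsity)
    if (any(colSums(C) == 0)) {
      abort("dictionary collapsed to a single stain", "wsikit_stain_error")
    }
    Dn <- nnls2_atoms(od, C)
    # project atoms onto the unit ball (scale lives in the codes)
    nrm <- sqrt(rowSums(Dn^2))
    assert_that(all(nrm > 1e-9), "degenerate dictionary atom",
                "wsikit_stain_error")
    Dn <- Dn / pmax(nrm, 1)
    delta <- max(abs(Dn / sqrt(rowSums(Dn^2)) - D / sqrt(rowSums(D^2))))
    D <- Dn
    obj <- sum((od - C %*% D)^2) + sparsity * sum(C)
    rel <- abs(obj_prev - obj) / max(obj, 1e-12)
    obj_prev <- obj
    if (delta < tol || rel < 1e-8) { converged <- TRUE; break }
  }
  D <- D / sqrt(rowSums(D^2))
  if (!converged) {
    abort(sprintf(
      "dictionary learning did not converge in %d iterations (last step %.2e)",
      max_iter, delta), "wsikit_convergence_error")
  }
  finalize_stain_matrix(D)
}

# Exact nonnegative lasso over two atoms, vectorised across pixels:
# per pixel minimise |x - c D|^2 + lambda * sum(c), c >= 0. The 2-variable
# KKT system is solved in closed form by comparing the interior solution
# with the two single-atom boundary solutions.
nnls2_codes <- function(X, D, lambda) {
  G <- D %*% t(D)
  b1 <- as.numeric(X %*% D[1, ]) - lambda / 2
  b2 <- as.numeric(X %*% D[2, ]) - lambda / 2
  det_g <- G[1, 1] * G[2, 2] - G[1, 2]^2
  c1 <- (G[2, 2] * b1 - G[1, 2] * b2) / det_g
  c2 <- (G[1, 1] * b2 - G[1, 2] * b1) / det_g
  interior <- c1 >= 0 & c2 >= 0
  # boundary candidates
  a1 <- pmax(0, b1 / G[1, 1])
  a2 <- pmax(0, b2 / G[2, 2])
  # objective difference (constant |x|^2 dropped): f(c) = c G c' - 2 c b
  f1 <- G[1, 1] * a1^2 - 2 * a1 * b1
  f2 <- G[2, 2] * a2^2 - 2 * a2 * b2
  use1 <- f1 <= f2
  C <- cbind(ifelse(use1, a1, 0), ifelse(use1, 0, a2))
  C[interior, 1] <- c1[interior]
  C[interior, 2] <- c2[interior]
  C
}

# Nonnegative least squares for the two atoms given codes: each of the three
# colour channels is an independent 2-variable NNLS with Gram crossprod(C).
nnls2_atoms <- function(X, C) {
  A <- crossprod(C)
  B <- crossprod(C, X)  # 2 x 3
  det_a <- A[1, 1] * A[2, 2] - A[1, 2]^2
  D <- matrix(0, 2, 3)
  for (j in 1:3) {
    d1 <- (A[2, 2] * B[1, j] - A[1, 2] * B[2, j]) / det_a
    d2 <- (A[1, 1] * B[2, j] - A[1, 2] * B[1, j]) / det_a
    if (d1 >= 0 && d2 >= 0) {
      D[, j] <- c(d1, d2)
    } else {
      a1 <- max(0, B[1, j] / A[1, 1])
      a2 <- max(0, B[2, j] / A[2, 2])
      f1 <- A[1, 1] * a1^2 - 2 * a1 * B[1, j]
      f2 <- A[2, 2] * a2^2 - 2 * a2 * B[2, j]
      D[, j] <- if (f1 <= f2) c(a1, 0) else c(0, a2)
    }
  }
  D
}

#' Ordinary-least-squares stain concentrations
#'
#' Solves `OD = C M` per pixel by OLS and clips negatives to zero.
#'
#' @param img RGB array, 0..255.
#' @param stain_matrix 2 x 3 (or k x 3) stain matrix.
#' @return `(h, w, k)` nonnegative concentration array.
#' @export
stain_concentrations <- function(img, stain_matrix) {
  img <- as_image_array(img)
  M <- as.matrix(stain_matrix)
  assert_that(ncol(M) == dim(img)[3], "stain matrix width must match channels")
  gram <- M %*% t(M)
  assert_that(abs(det(gram)) > 1e-12, "singular stain matrix")
  od <- matrix(rgb_to_od(img), ncol = dim(img)[3])
  C <- od %*% t(M) %*% solve(gram)
  C[C < 0] <- 0
  array(C, c(dim(img)[1], dim(img)[2], nrow(M)))
}

# --- normalizers ------------------------------------------------------------

#' Stain normalizers
#'
#' `stain_normalizer()` creates an unfitted normalizer; [stain_fit()] learns
#' the target appearance from a reference image and [stain_transform()] maps
#' source images onto it.
#'
#' Methods: `"reinhard"` matches per-channel mean and standard deviation in
#' LAB space. The matrix-based methods (`"macenko"`, `"vahadane"` --
#' the dictionary-learning variant -- and `"custom"`) estimate source
#' concentrations by OLS, rescale each stain by the ratio of the target and
#' source 99th-percentile concentrations, and reconstruct with the target
#' stain matrix.
#'
#' @param method normalization method.
#' @param stain_matrix 2 x 3 matrix for `method = "custom"`.
#' @return a `stain_normalizer` object.
#' @export
stain_normalizer <- function(method = c("reinhard", "macenko", "vahadane",
                                        "custom"),
                             stain_matrix = NULL) {
  method <- match.arg(method)
  if (method == "custom") {
    assert_that(!is.null(stain_matrix), "custom method requires stain_matrix")
  }
  structure(list(method = method, stain_matrix = stain_matrix,
                 fitted = FALSE),
            class = "stain_normalizer")
}

rgb_to_lab <- function(img) {
  img <- as_image_array(img)
  px <- matrix(img, ncol = 3) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  array(lab, dim(img))
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  px <- grDevices::convertColor(matrix(lab, ncol = 3), from = "Lab",
                                to = "sRGB")
  quantize_8bit(array(px * 255, d))
}

matrix_for <- function(norm, img) {
  switch(norm$method,
         macenko = macenko_matrix(img),
         vahadane = dictionary_matrix(img),
         custom = finalize_stain_matrix(as.matrix(norm$stain_matrix)),
         abort("not a matrix-based method", "wsikit_state_error"))
}

#' @rdname stain_normalizer
#' @param norm a `stain_normalizer`.
#' @param target_img target RGB image defining the appearance to map onto.
#' @export
stain_fit <- function(norm, target_img) {
  assert_that(inherits(norm, "stain_normalizer"), "not a stain_normalizer")
  target_img <- as_image_array(target_img)
  if (norm$method == "reinhard") {
    lab <- matrix(rgb_to_lab(target_img), ncol = 3)
    norm$target_mean <- colMeans(lab)
    norm$target_sd <- apply(lab, 2, stats::sd)
    assert_that(all(norm$target_sd > 0), "degenerate target image")
  } else {
    M <- matrix_for(norm, target_img)
    C <- matrix(stain_concentrations(target_img, M), ncol = nrow(M))
    norm$target_matrix <- M
    norm$target_p99 <- apply(C, 2, stats::quantile, probs = 0.99,
                             names = FALSE)
  }
  norm$fitted <- TRUE
  norm
}

#' @rdname stain_normalizer
#' @param src_img source RGB image to normalize.
#' @export
stain_transform <- function(norm, src_img) {
  assert_that(inherits(norm, "stain_normalizer"), "not a stain_normalizer")
  if (!isTRUE(norm$fitted)) {
    abort("stain_transform() called before stain_fit()",
          "wsikit_state_error")
  }
  src_img <- as_image_array(src_img)
  d <- dim(src_img)
  if (norm$method == "reinhard") {
    lab <- matrix(rgb_to_lab(src_img), ncol = 3)
    mu <- colMeans(lab)
    sd <- apply(lab, 2, stats::sd)
    sd[sd == 0] <- 1
    lab <- sweep(lab, 2, mu)
    lab <- sweep(lab, 2, norm$target_sd / sd, `*`)
    lab <- sweep(lab, 2, norm$target_mean, `+`)
    return(lab_to_rgb(array(lab, d)))
  }
  Ms <- matrix_for(norm, src_img)
  C <- matrix(stain_concentrations(src_img, Ms), ncol = nrow(Ms))
  p99 <- apply(C, 2, stats::quantile, probs = 0.99, names = FALSE)
  p99[p99 == 0] <- 1
  C <- sweep(C, 2, norm$target_p99 / p99, `*`)
  od <- C %*% norm$target_matrix
  od_to_rgb(array(od, d))
}

#' Stain augmentation by concentration perturbation
#'
#' Estimates the source stain matrix and concentrations, perturbs each
#' stain's concentration channel as `C' = alpha * C + beta` with
#' `alpha ~ U(1 - sigma_alpha, 1 + sigma_alpha)` and
#' `beta ~ U(-sigma_beta, sigma_beta)` (clipped at zero), and reconstructs
#' with the source matrix. Background pixels (OD norm below `od_min`) are
#' exempt from the additive shift so glass is not tinted. Deterministic for
#' a fixed seed. Images without enough tissue to decompose are passed
#' through with a warning.
#'
#' @param img RGB array, 0..255.
#' @param sigma_alpha,sigma_beta perturbation half-widths.
#' @param seed integer seed.
#' @param od_min background OD cutoff.
#' @return perturbed RGB array.
#' @export
stain_augment <- function(img, sigma_alpha = 0.2, sigma_beta = 0.2,
                          seed = 1L, od_min = 0.15) {
  img <- as_image_array(img)
  M <- tryCatch(macenko_matrix(img, od_min = od_min),
                wsikit_error = function(e) {
                  warning("insufficient tissue for stain augmentation; ",
                          "returning the image unchanged", call. = FALSE)
                  NULL
                })
  if (is.null(M)) return(img)
  d <- dim(img)
  C <- matrix(stain_concentrations(img, M), ncol = 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alpha <- stats::runif(2, 1 - sigma_alpha, 1 + sigma_alpha)
  beta <- stats::runif(2, -sigma_beta, sigma_beta)
  od <- matrix(rgb_to_od(img), ncol = 3)
  tissue <- sqrt(rowSums(od^2)) > od_min
  for (s in 1:2) {
    C[, s] <- C[, s] * alpha[s] + ifelse(tissue, beta[s], 0)
  }
  C[C < 0] <- 0
  od_to_rgb(array(C %*% M, d))
}
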