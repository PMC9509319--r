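# Reference models satisfying the model contract. They are deliberately
# simple, deterministic, CPU-only functions so the whole inference engine is
# testable without any deep-learning runtime; external models plug in by
# satisfying the same contract.

#' Model contract
#'
#' Declares everything the engine needs to run a patch-level model: the task
#' kind, input geometry and resolution, output arity, and a pure batched
#' inference function (`length(out) == length(batch)`, same inputs give the
#' same outputs). Per-pixel models may declare a `margin`: output pixels
#' within `margin` of a tile edge have an incomplete receptive field and are
#' emitted as `NA`, which the tiled merger excludes from overlap averaging.
#'
#' @param task `"patch_label"`, `"per_pixel"`, `"feature"` or `"instance"`.
#' @param input_size `(w, h)` expected patch size, or `NULL` for any.
#' @param input_resolution a [resolution()] patches should be read at.
#' @param output_channels length of the per-patch/per-pixel output.
#' @param infer_batch `function(list of images) -> list of outputs`.
#' @param postprocess optional `function(raw) -> final` applied per output.
#' @param margin receptive-field margin for per-pixel models (pixels).
#' @param name model name used in serialized records.
#' @return a `model_contract`.
#' @export
model_contract <- function(task = c("patch_label", "per_pixel", "feature",
                                    "instance"),
                           input_size = NULL,
                           input_resolution = resolution(1, "baseline"),
                           output_channels = 1L,
                           infer_batch, postprocess = NULL, margin = 0L,
                           name = "custom") {
  task <- match.arg(task)
  assert_that(is.function(infer_batch), "infer_batch must be a function")
  if (!is.null(input_size)) input_size <- per_axis(input_size, "input_size")
  structure(list(task = task, input_size = input_size,
                 input_resolution = as_resolution(input_resolution),
                 output_channels = as.integer(output_channels),
                 infer_batch = infer_batch, postprocess = postprocess,
                 margin = as.integer(margin), name = name),
            class = "model_contract")
}

#' Reference models
#'
#' `model_mean_intensity()` is a two-class patch classifier: the "tissue"
#' probability is `1 - mean(patch) / 255`, so patches darker than the
#' threshold are labelled class 2 (tissue). `model_mean_filter()` is a
#' translation-equivariant per-pixel model (k x k box filter per channel,
#' `NA` margin). `model_histogram()` extracts an `3 * bins` colour histogram
#' feature per patch.
#'
#' @param threshold mean-intensity decision threshold (0..255).
#' @param input_size patch size declared to the engine.
#' @param input_resolution resolution patches are read at.
#' @return a [model_contract()].
#' @export
model_mean_intensity <- function(threshold = 127.5, input_size = NULL,
                                 input_resolution = resolution(1, "baseline")) {
  model_contract(
    task = "patch_label", input_size = input_size,
    input_resolution = input_resolution, output_channels = 2L,
    infer_batch = function(batch) {
      lapply(batch, function(img) {
        # calibrated so that argmax switches exactly at `threshold`
        p <- clamp(0.5 + (threshold - mean(img)) / 255, 0, 1)
        c(background = 1 - p, tissue = p)
      })
    },
    name = "mean-intensity")
}

#' @rdname model_mean_intensity
#' @param k box-filter side (odd).
#' @export
model_mean_filter <- function(k = 3L,
                              input_resolution = resolution(1, "baseline")) {
  assert_that(k %% 2 == 1 && k >= 1, "k must be odd and >= 1")
  half <- (k - 1L) %/% 2L
  model_contract(
    task = "per_pixel", input_resolution = input_resolution,
    output_channels = 3L, margin = half,
    infer_batch = function(batch) {
      lapply(batch, function(img) {
        img <- as_image_array(img)
        d <- dim(img)
        out <- array(NA_real_, d)
        if (d[1] < k || d[2] < k) return(out)
        for (ch in seq_len(d[3])) {
          plane <- img[, , ch]
          acc <- matrix(0, d[1] - k + 1L, d[2] - k + 1L)
          for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
            acc <- acc + plane[(1 + dy):(d[1] - k + 1L + dy),
                               (1 + dx):(d[2] - k + 1L + dx)]
          }
          out[(half + 1L):(d[1] - half), (half + 1L):(d[2] - half), ch] <-
            acc / (k * k)
        }
        out
      })
    },
    name = sprintf("mean-filter-%d", k))
}

#' @rdname model_mean_intensity
#' @param bins histogram bins per channel.
#' @export
model_histogram <- function(bins = 8L,
                            input_resolution = resolution(1, "baseline")) {
  model_contract(
    task = "feature", input_resolution = input_resolution,
    output_channels = 3L * bins,
    infer_batch = function(batch) {
      lapply(batch, function(img) {
        img <- as_image_array(img)
        unlist(lapply(seq_len(dim(img)[3]), function(ch) {
          idx <- pmin(floor(img[, , ch] / (256 / bins)), bins - 1) + 1L
          tabulate(idx, nbins = bins) / length(idx)
        }))
      })
    },
    name = sprintf("histogram-%d", bins))
}
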