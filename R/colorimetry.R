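#' Colorimetric analysis configuration
#'
#' Parameters of the per-pixel threshold mixing analysis.
#'
#' @param mixing_coefficient `X` in `[0, 1]`: fractional position of the
#'   per-pixel threshold between the initial and final gray value. `X = 0.5`
#'   (default) places it halfway, which for the blue-to-colorless
#'   decolorization assay agrees with naked-eye judgement of "mixed".
#' @param mixed_level percent-mixed level defining the endpoint; default 90,
#'   i.e. t90 is the first frame with at least 90% of valid pixels mixed.
#' @param static_epsilon gray levels: pixels whose total change between the
#'   first and last reference frames is below this are treated as static
#'   (rotor shaft, vessel wall, ...) and excluded from the analysis;
#'   default 10.
#' @param reference_last_n number of trailing frames averaged to form the
#'   fully-mixed reference; default 1 (the literal last frame).
#' @param strict if `TRUE` (default) a pixel is mixed when its gray value
#'   strictly exceeds its threshold; `FALSE` uses `>=`.
#' @param grayscale_weights RGB luma weights, see [to_grayscale()].
#' @return an object of class `colorimetry_config`.
#' @export
colorimetry_config <- function(mixing_coefficient = 0.5, mixed_level = 90,
                               static_epsilon = 10, reference_last_n = 1L,
                               strict = TRUE,
                               grayscale_weights = c(0.299, 0.587, 0.114)) {
  stopifnot(
    mixing_coefficient >= 0, mixing_coefficient <= 1,
    mixed_level > 0, mixed_level <= 100,
    static_epsilon >= 0, reference_last_n >= 1L,
    abs(sum(grayscale_weights) - 1) < 1e-8
  )
  structure(
    list(mixing_coefficient = mixing_coefficient, mixed_level = mixed_level,
         static_epsilon = static_epsilon,
         reference_last_n = as.integer(reference_last_n), strict = strict,
         grayscale_weights = grayscale_weights),
    class = "colorimetry_config"
  )
}

#' Per-pixel discoloration threshold map
#'
#' Each pixel gets its own threshold interpolated between its initial gray
#' value `R0` (first frame) and its fully-mixed value `Rinf` (last frame, or
#' the mean of the trailing `reference_last_n` frames):
#' `beta = R0 + X * (Rinf - R0)`.
#' Pixels with `|Rinf - R0| < static_epsilon` show no discoloration signal
#' — their threshold would be noise-dominated — and are flagged invalid. An
#' ROI mask on the stack is intersected into the validity mask.
#'
#' @param stack a [frame_stack()].
#' @param config a [colorimetry_config()].
#' @return an object of class `threshold_map` with fields `beta` (`H x W`
#'   numeric) and `valid` (`H x W` logical).
#' @export
threshold_map <- function(stack, config = colorimetry_config()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(config, "colorimetry_config"))
  d <- dim(stack$frames)
  n <- d[3L]
  r0 <- matrix(stack$frames[, , 1L], d[1L], d[2L])
  nref <- min(config$reference_last_n, n - 1L)
  if (nref == 1L) {
    rinf <- matrix(stack$frames[, , n], d[1L], d[2L])
  } else {
    tail_idx <- (n - nref + 1L):n
    rinf <- matrix(apply(stack$frames[, , tail_idx, drop = FALSE],
                         c(1L, 2L), mean), d[1L], d[2L])
  }
  valid <- abs(rinf - r0) >= config$static_epsilon
  if (!is.null(stack$roi_mask)) valid <- valid & stack$roi_mask
  if (!any(valid))
    stop_dissolvr("no dynamic pixels: every pixel is static within epsilon",
                  "dissolvr_no_dynamics")
  beta <- r0 + config$mixing_coefficient * (rinf - r0)
  structure(list(beta = beta, valid = valid, r0 = r0, rinf = rinf,
                 config = config),
            class = "threshold_map")
}

#' @export
print.threshold_map <- function(x, ...) {
  cat(sprintf("<threshold_map> %d x %d px, %d valid (%.1f%%), X = %g\n",
              nrow(x$beta), ncol(x$beta), sum(x$valid),
              100 * mean(x$valid), x$config$mixing_coefficient))
  invisible(x)
}

#' Per-frame mixed/unmixed pixel classification
#'
#' Classifies every pixel in every frame independently (no latching): mixed
#' when its gray value exceeds its individual threshold. Invalid pixels are
#' always 0.
#'
#' @param stack a [frame_stack()].
#' @param tmap a [threshold_map()] computed from the same stack geometry.
#' @return logical `H x W x T` array.
#' @export
classify_mixed <- function(stack, tmap) {
  stopifnot(inherits(stack, "frame_stack"), inherits(tmap, "threshold_map"))
  d <- dim(stack$frames)
  if (!identical(d[1:2], dim(tmap$beta)))
    stop_dissolvr("stack and threshold map shapes disagree", "dissolvr_shape_mismatch")
  # beta (H x W) recycles along the frame axis in column-major order
  bin <- if (tmap$config$strict) stack$frames > c(tmap$beta)
         else stack$frames >= c(tmap$beta)
  bin & c(tmap$valid)
}

#' Percent-mixed curve M(t)
#'
#' For each frame, the percentage of valid pixels classified as mixed:
#' `M_k = 100 * (# mixed valid pixels in frame k) / n_valid`.
#'
#' @param binary logical `H x W x T` array from [classify_mixed()].
#' @param tmap the [threshold_map()] supplying the validity mask.
#' @param fps frame rate, or a [frame_stack()] to take timing from.
#' @param t0_offset first-frame time, seconds.
#' @return an object of class `mixing_curve` with fields `times`, `M`
#'   (percent) and `n_valid`.
#' @export
mixing_curve <- function(binary, tmap, fps, t0_offset = 0) {
  stopifnot(is.array(binary), length(dim(binary)) == 3L,
            inherits(tmap, "threshold_map"))
  if (inherits(fps, "frame_stack")) {
    t0_offset <- fps$t0_offset
    fps <- fps$fps
  }
  d <- dim(binary)
  n_valid <- sum(tmap$valid)
  if (n_valid == 0L)
    stop_dissolvr("zero valid pixels in denominator", "dissolvr_no_dynamics")
  mat <- matrix(binary, nrow = d[1L] * d[2L], ncol = d[3L])
  counts <- colSums(mat[c(tmap$valid), , drop = FALSE])
  structure(
    list(times = t0_offset + (seq_len(d[3L]) - 1L) / fps,
         M = 100 * counts / n_valid, n_valid = n_valid, fps = fps,
         t0_offset = t0_offset),
    class = "mixing_curve"
  )
}

#' @export
print.mixing_curve <- function(x, ...) {
  cat(sprintf("<mixing_curve> %d frames, n_valid = %d, final M = %.1f%%\n",
              length(x$M), x$n_valid, x$M[length(x$M)]))
  invisible(x)
}

#' Discoloration time t90
#'
#' The mixing time is the time of the first frame whose percent-mixed value
#' reaches `mixed_level` (default 90%). No interpolation: the resolution is
#' one frame interval. If the level is never reached the result is censored
#' at the video duration, with `censored = TRUE` — censoring is a valid
#' outcome, mirroring the fixed observation window of the conductometric
#' assay.
#'
#' @param curve a [mixing_curve()].
#' @param config a [colorimetry_config()]; only `mixed_level` is used.
#' @return an object of class `discoloration_result` with fields `t90`,
#'   `censored`, `frame_index` (0-based, `NA` if censored), `curve`,
#'   `n_valid`, `config`.
#' @export
discoloration_time <- function(curve, config = colorimetry_config()) {
  stopifnot(inherits(curve, "mixing_curve"))
  level <- if (inherits(config, "colorimetry_config")) config$mixed_level else config
  idx <- first_crossing_index(curve$M, level)
  censored <- is.na(idx)
  duration <- curve$t0_offset + length(curve$M) / curve$fps
  structure(
    list(t90 = if (censored) duration else curve$times[idx],
         censored = censored,
         frame_index = if (censored) NA_integer_ else idx - 1L,
         curve = curve, n_valid = curve$n_valid, level = level,
         config = if (inherits(config, "colorimetry_config")) config else NULL),
    class = "discoloration_result"
  )
}

#' @export
print.discoloration_result <- function(x, ...) {
  if (x$censored)
    cat(sprintf("<discoloration_result> censored at %.4f s (M never reached %g%%)\n",
                x$t90, x$level))
  else
    cat(sprintf("<discoloration_result> t90 = %.4f s (frame %d, n_valid = %d)\n",
                x$t90, x$frame_index, x$n_valid))
  invisible(x)
}

#' First-mixed time map
#'
#' For every valid pixel, the acquisition time of the first frame in which it
#' was classified as mixed (later flicker is ignored). Pixels that never mix,
#' and invalid pixels, carry `NA`. These maps reproduce the contour views of
#' spatial mixing progress around the rotor.
#'
#' @param binary logical `H x W x T` array from [classify_mixed()].
#' @param fps frame rate, or a [frame_stack()] to take timing from.
#' @param t0_offset first-frame time, seconds.
#' @return `H x W` numeric matrix of first-mixed times (s), class
#'   `first_mixed_map`; `NA` = never mixed / invalid.
#' @export
first_mixed_map <- function(binary, fps, t0_offset = 0) {
  stopifnot(is.array(binary), length(dim(binary)) == 3L)
  if (inherits(fps, "frame_stack")) {
    t0_offset <- fps$t0_offset
    fps <- fps$fps
  }
  d <- dim(binary)
  mat <- matrix(binary, nrow = d[1L] * d[2L], ncol = d[3L])
  first <- rep(NA_integer_, nrow(mat))
  for (k in seq_len(d[3L])) {
    hit <- is.na(first) & mat[, k]
    if (any(hit)) first[hit] <- k
  }
  out <- matrix(t0_offset + (first - 1L) / fps, nrow = d[1L], ncol = d[2L])
  structure(out, class = c("first_mixed_map", "matrix"))
}

#' End-to-end colorimetric analysis of one video
#'
#' Convenience wrapper chaining [threshold_map()], [classify_mixed()],
#' [mixing_curve()], [discoloration_time()] and [first_mixed_map()].
#'
#' @param stack a grayscale [frame_stack()] (apply [crop_roi()] first if
#'   needed).
#' @param config a [colorimetry_config()].
#' @param roi optional ROI passed to [crop_roi()].
#' @return a list with `result` ([discoloration_time()] output), `curve`,
#'   `tmap` and `first_mixed`.
#' @export
analyze_video <- function(stack, config = colorimetry_config(), roi = NULL) {
  if (!is.null(roi)) stack <- crop_roi(stack, roi)
  tmap <- threshold_map(stack, config)
  bin <- classify_mixed(stack, tmap)
  curve <- mixing_curve(bin, tmap, stack)
  res <- discoloration_time(curve, config)
  list(result = res, curve = curve, tmap = tmap,
       first_mixed = first_mixed_map(bin, stack))
}
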