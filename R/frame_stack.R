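#' Time-ordered grayscale frame stack
#'
#' The container for discoloration video data: an `H x W x T` numeric array
#' of gray values in `[0, 255]` plus the acquisition frame rate. Frame `k`
#' (0-based) was acquired at time `t0_offset + k / fps` seconds. Values are
#' stored as numeric, not integer: 8-bit sources yield whole numbers, while
#' synthetic noiseless videos keep sub-gray-level precision so that analytic
#' ground truth is matched exactly.
#'
#' @param frames numeric `H x W x T` array of gray values, `T >= 2`.
#' @param fps frames per second, > 0.
#' @param t0_offset acquisition time of the first frame, seconds.
#' @param roi_mask optional `H x W` logical mask restricting the region of
#'   interest; pixels outside the mask are excluded downstream.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, t0_offset = 0, roi_mask = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3L] < 2L)
    stop_dissolvr("a frame stack needs at least 2 frames", "dissolvr_too_few_frames")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop_dissolvr("fps must be a single positive number", "dissolvr_bad_fps")
  rng <- range(frames)
  if (rng[1L] < 0 || rng[2L] > 255)
    stop_dissolvr("gray values must lie in [0, 255]", "dissolvr_gray_range")
  if (!is.null(roi_mask)) {
    stopifnot(is.logical(roi_mask))
    if (!identical(dim(roi_mask), dim(frames)[1:2]))
      stop_dissolvr("roi_mask shape must equal frame shape", "dissolvr_roi_shape")
  }
  structure(
    list(frames = frames, fps = fps, t0_offset = t0_offset, roi_mask = roi_mask),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d x %d px, %d frames @ %g fps (%.3f s)\n",
    d[1L], d[2L], d[3L], x$fps, d[3L] / x$fps
  ))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Frame acquisition times of a stack
#' @param stack a [frame_stack()].
#' @return numeric vector of length T, seconds.
#' @export
frame_times <- function(stack) {
  n <- dim(stack$frames)[3L]
  stack$t0_offset + (seq_len(n) - 1L) / stack$fps
}

#' Load a frame stack from an image-sequence directory
#'
#' Reads all frames from `source`, ordered lexicographically by file name
#' (zero-padded numbering is assumed, as produced by [write_frames()]).
#' Supported per-frame formats, decided from the file extension:
#' * `.pgm` — plain (P2) or raw (P5) portable graymap;
#' * `.csv` — a bare numeric matrix, one row per pixel row;
#' * `.png` — 8/16-bit grayscale or RGB PNG (needs the `png` package).
#'
#' 16-bit sources are rescaled to the 0-255 range with a warning. RGB frames
#' are converted with [to_grayscale()] using default weights.
#'
#' @param source directory containing the image sequence.
#' @param fps frame rate override; required, since none of the supported
#'   still-image formats carries timing metadata.
#' @param pattern optional regular expression selecting frame files.
#' @return a [frame_stack()].
#' @export
load_frames <- function(source, fps, pattern = "\\.(pgm|csv|png)$") {
  if (!dir.exists(source))
    stop_dissolvr(sprintf("frame source '%s' does not exist", source),
                  "dissolvr_missing_source")
  if (missing(fps) || is.null(fps))
    stop_dissolvr("fps cannot be resolved from still images; pass fps=",
                  "dissolvr_fps_unresolvable")
  files <- sort(list.files(source, pattern = pattern, full.names = TRUE))
  if (length(files) < 2L)
    stop_dissolvr("need at least 2 frames", "dissolvr_too_few_frames")
  mats <- lapply(files, read_frame_file)
  shp <- dim(mats[[1L]])
  ok <- vapply(mats, function(m) identical(dim(m), shp), logical(1L))
  if (!all(ok))
    stop_dissolvr(
      sprintf("inconsistent frame shapes (first mismatch: '%s')",
              basename(files[which(!ok)[1L]])),
      "dissolvr_shape_mismatch"
    )
  frames <- array(unlist(mats, use.names = FALSE), dim = c(shp, length(mats)))
  frame_stack(frames, fps = fps)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    pgm = read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    png = read_png_gray(path),
    stop_dissolvr(sprintf("unreadable frame '%s': unsupported format", path),
                  "dissolvr_unreadable_frame")
  )
  if (!is.numeric(m) || anyNA(m))
    stop_dissolvr(sprintf("unreadable frame '%s'", path), "dissolvr_unreadable_frame")
  if (max(m) > 255) {
    warning(sprintf("'%s': >8-bit values, rescaling to 0-255", basename(path)))
    m <- m / 257  # 16-bit full scale 65535 -> 255
  }
  m
}

read_png_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_dissolvr("reading PNG frames requires the 'png' package",
                  "dissolvr_unreadable_frame")
  a <- png::readPNG(path) * 255
  if (length(dim(a)) == 3L) {  # RGB(A): drop alpha, apply default luma weights
    w <- c(0.299, 0.587, 0.114)
    a <- round_half_up(w[1L] * a[, , 1L] + w[2L] * a[, , 2L] + w[3L] * a[, , 3L])
  }
  a
}

#' Convert an RGB stack to grayscale
#'
#' Collapses an RGB frame stack to single-channel gray values by a weighted
#' channel sum, rounded half-up to whole gray levels (emulating the 8-bit
#' quantization of camera pipelines). Default weights are the ITU-R BT.601
#' luma coefficients.
#'
#' @param rgb either an `H x W x 3 x T` numeric array (values 0-255), the
#'   `rgb_stack` produced by [render_rgb()], or an already-gray
#'   [frame_stack()] (returned unchanged).
#' @param weights length-3 channel weights summing to 1.
#' @param fps,t0_offset timing metadata for bare arrays; taken from the input
#'   when it already carries them.
#' @return a grayscale [frame_stack()].
#' @export
to_grayscale <- function(rgb, weights = c(0.299, 0.587, 0.114),
                         fps = NULL, t0_offset = 0) {
  if (inherits(rgb, "frame_stack")) return(rgb)
  if (inherits(rgb, "rgb_stack")) {
    fps <- fps %||% attr(rgb, "fps")
    t0_offset <- attr(rgb, "t0_offset") %||% t0_offset
    rgb <- unclass(rgb)
  }
  stopifnot(is.array(rgb), length(dim(rgb)) == 4L)
  if (dim(rgb)[3L] != 3L)
    stop_dissolvr("expected 3 color channels", "dissolvr_bad_channels")
  if (abs(sum(weights) - 1) > 1e-8)
    stop_dissolvr("grayscale weights must sum to 1", "dissolvr_bad_weights")
  d <- dim(rgb)
  gray <- weights[1L] * rgb[, , 1L, , drop = FALSE] +
    weights[2L] * rgb[, , 2L, , drop = FALSE] +
    weights[3L] * rgb[, , 3L, , drop = FALSE]
  gray <- round_half_up(array(gray, dim = d[c(1L, 2L, 4L)]))
  frame_stack(gray, fps = fps %||% stop_dissolvr("fps unresolvable", "dissolvr_bad_fps"),
              t0_offset = t0_offset)
}

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle `[row0, row0 + height) x [col0, col0 + width)`
#' in pixel coordinates, matching the (row, col) convention used throughout.
#'
#' @param row0,col0 top-left corner, 0-based.
#' @param height,width extent in pixels, >= 1.
#' @return an object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, height, width) {
  stopifnot(row0 >= 0, col0 >= 0, height >= 1, width >= 1)
  structure(list(row0 = row0, col0 = col0, height = height, width = width),
            class = "roi_rect")
}

#' Crop a frame stack to a region of interest
#'
#' Rectangles subset the pixel array; logical masks keep the full array but
#' record the mask, which downstream analysis combines with the dynamic-pixel
#' mask so that out-of-ROI pixels never enter the percent-mixed denominator.
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi_rect()] or an `H x W` logical mask.
#' @return a cropped [frame_stack()].
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (inherits(roi, "roi_rect")) {
    if (roi$row0 + roi$height > d[1L] || roi$col0 + roi$width > d[2L])
      stop_dissolvr("roi exceeds frame bounds", "dissolvr_roi_bounds")
    rows <- (roi$row0 + 1L):(roi$row0 + roi$height)
    cols <- (roi$col0 + 1L):(roi$col0 + roi$width)
    mask <- if (is.null(stack$roi_mask)) NULL else stack$roi_mask[rows, cols, drop = FALSE]
    frame_stack(stack$frames[rows, cols, , drop = FALSE], fps = stack$fps,
                t0_offset = stack$t0_offset, roi_mask = mask)
  } else if (is.logical(roi) && is.matrix(roi)) {
    if (!identical(dim(roi), d[1:2]))
      stop_dissolvr("roi mask shape must equal frame shape", "dissolvr_roi_shape")
    mask <- if (is.null(stack$roi_mask)) roi else roi & stack$roi_mask
    frame_stack(stack$frames, fps = stack$fps, t0_offset = stack$t0_offset,
                roi_mask = mask)
  } else {
    stop_dissolvr("roi must be a roi_rect or a logical matrix", "dissolvr_bad_roi")
  }
}
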