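# Readers and writers for the package's on-disk formats. All formats are
# plain text; times are serialized in seconds with 6 decimal places so the
# 1/60 s frame grid and 10 ms sample grids survive round trips.

fmt_time <- function(x) round(x, 6)

#' Read a plain (P2) portable graymap
#'
#' Minimal text-PGM reader for frame sequences; `#` comments are honored.
#' Sources with `maxval > 255` are rescaled to 0-255 (with a warning from
#' [load_frames()]).
#'
#' @param path file path.
#' @return numeric matrix of gray values.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1L] != "P2")
    stop_dissolvr(sprintf("'%s' is not a plain (P2) PGM", path),
                  "dissolvr_unreadable_frame")
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  maxval <- as.numeric(tok[4L])
  px <- as.numeric(tok[-(1:4)])
  if (anyNA(px) || length(px) != w * h)
    stop_dissolvr(sprintf("corrupt PGM '%s'", path), "dissolvr_unreadable_frame")
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  if (maxval > 255) m <- m * (65535 / maxval)  # promote to 16-bit scale;
  m                                            # load_frames rescales + warns
}

#' Write a matrix as a plain (P2) portable graymap
#'
#' Values are rounded half-up to integers and clipped to `[0, maxval]`.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param maxval maximum gray value, default 255.
#' @export
write_pgm <- function(mat, path, maxval = 255L) {
  m <- pmin(pmax(round_half_up(mat), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a frame stack as a numbered image sequence
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if missing).
#' @param format `"pgm"` (plain text, default) or `"png"` (requires the
#'   `png` package).
#' @param prefix file-name prefix; frames are zero-padded so lexicographic
#'   order is acquisition order.
#' @return invisibly, the written file paths.
#' @export
write_frames <- function(stack, dir, format = c("pgm", "png"),
                         prefix = "frame_") {
  stopifnot(inherits(stack, "frame_stack"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(stack$frames)[3L]
  width <- max(4L, nchar(as.character(n - 1L)))
  paths <- file.path(dir, sprintf("%s%0*d.%s", prefix, width,
                                  seq_len(n) - 1L, format))
  for (i in seq_len(n)) {
    if (format == "pgm") {
      write_pgm(stack$frames[, , i], paths[i])
    } else {
      if (!requireNamespace("png", quietly = TRUE))
        stop_dissolvr("writing PNG requires the 'png' package",
                      "dissolvr_unreadable_frame")
      m <- matrix(stack$frames[, , i], dim(stack$frames)[1L])
      png::writePNG(pmin(pmax(round_half_up(m), 0), 255) / 255, paths[i])
    }
  }
  invisible(paths)
}

#' Write a mixing curve as CSV
#'
#' Columns: `frame_index` (0-based), `time_s`, `M_percent`.
#' @param curve a [mixing_curve()].
#' @param path output path.
#' @export
write_mixing_curve <- function(curve, path) {
  stopifnot(inherits(curve, "mixing_curve"))
  df <- data.frame(frame_index = seq_along(curve$M) - 1L,
                   time_s = fmt_time(curve$times),
                   M_percent = round(curve$M, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mixing curve written by [write_mixing_curve()]
#' @param path CSV path.
#' @param fps frame rate to reattach (defaults to the reciprocal median
#'   time step).
#' @return a [mixing_curve()]-compatible object (without validity counts).
#' @export
read_mixing_curve <- function(path, fps = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame_index", "time_s", "M_percent") %in% names(df)))
  fps <- fps %||% (1 / stats::median(diff(df$time_s)))
  structure(list(times = df$time_s, M = df$M_percent, n_valid = NA_integer_,
                 fps = fps, t0_offset = df$time_s[1L]),
            class = "mixing_curve")
}

#' Write a discoloration result as JSON
#' @param result a [discoloration_time()] result.
#' @param path output path.
#' @param input_digest optional digest string identifying the input video.
#' @export
write_discoloration_json <- function(result, path, input_digest = NULL) {
  stopifnot(inherits(result, "discoloration_result"))
  cfg <- result$config
  obj <- list(
    t90_s = fmt_time(result$t90), censored = result$censored,
    frame_index = result$frame_index, n_valid = result$n_valid,
    level_percent = result$level,
    config = if (is.null(cfg)) NULL else cfg[c(
      "mixing_coefficient", "mixed_level", "static_epsilon",
      "reference_last_n", "strict")],
    input_digest = input_digest
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a first-mixed map as a CSV matrix
#'
#' Never-mixed / invalid pixels are written as empty cells.
#' @param fmap a [first_mixed_map()].
#' @param path output path.
#' @export
write_first_mixed_csv <- function(fmap, path) {
  utils::write.table(fmt_time(unclass(fmap)), path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write conductivity traces to the CSV layout read by [load_traces()]
#' @param traces list of [conductivity_trace()] objects.
#' @param path output path.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    df <- data.frame(run_id = tr$metadata$run_id %||% "run1",
                     time_s = fmt_time(tr$times),
                     conductivity = tr$values)
    for (f in setdiff(names(tr$metadata), "run_id")) df[[f]] <- tr$metadata[[f]]
    df
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(df) {
    for (f in setdiff(all_cols, names(df))) df[[f]] <- NA
    df[all_cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a factorial design table
#' @param design data.frame as produced by [synth_design()].
#' @param path CSV path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path))
    stop_dissolvr(sprintf("design file '%s' does not exist", path),
                  "dissolvr_missing_source")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an effects report as CSV
#' @param report an `effects_report` from [factorial_effects()].
#' @param path output path.
#' @export
write_effects_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
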