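#' Raw conductivity trace of one dissolution run
#'
#' @param times sample times in seconds, strictly increasing (uniform
#'   sampling is not assumed; microcontroller acquisition jitters).
#' @param values raw conductivity readout, arbitrary instrument units, >= 0.
#' @param metadata named list of run descriptors (solvent,
#'   `viscosity_mPas`, `rpm`, `particle_class`, `temp_C`, `compound`,
#'   `vessel`, `run_id`, ...). Free-form; used for grouping in
#'   [batch_dissolution()].
#' @return an object of class `conductivity_trace`.
#' @export
conductivity_trace <- function(times, values, metadata = list()) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values) || length(times) < 2L)
    stop_dissolvr("times and values must have equal length >= 2",
                  "dissolvr_bad_trace")
  if (anyNA(times) || anyNA(values))
    stop_dissolvr("non-numeric or missing samples in trace", "dissolvr_bad_trace")
  if (is.unsorted(times, strictly = TRUE))
    stop_dissolvr("times must be strictly increasing", "dissolvr_bad_trace")
  structure(list(times = times, values = values, metadata = metadata),
            class = "conductivity_trace")
}

#' @export
print.conductivity_trace <- function(x, ...) {
  cat(sprintf("<conductivity_trace> %d samples over %.2f s [run %s]\n",
              length(x$times), diff(range(x$times)),
              x$metadata$run_id %||% "?"))
  invisible(x)
}

#' Load conductivity traces from a CSV file
#'
#' Expects columns `run_id`, `time_s`, `conductivity`; any further columns
#' (`solvent`, `viscosity_mPas`, `rpm`, `particle_class`, `temp_C`,
#' `compound`, `vessel`) are carried as per-run metadata (they must be
#' constant within a run). Rows are sorted by time within each run;
#' duplicated timestamps within a run are rejected.
#'
#' @param path CSV file path.
#' @return named list of [conductivity_trace()] objects, one per `run_id`.
#' @export
load_traces <- function(path) {
  if (!file.exists(path))
    stop_dissolvr(sprintf("trace file '%s' does not exist", path),
                  "dissolvr_missing_source")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "time_s", "conductivity")
  if (!all(need %in% names(df)))
    stop_dissolvr(sprintf("trace CSV must have columns %s",
                          paste(need, collapse = ", ")), "dissolvr_bad_trace")
  if (!is.numeric(df$time_s) || !is.numeric(df$conductivity) ||
      anyNA(df$time_s) || anyNA(df$conductivity))
    stop_dissolvr("non-numeric cells in time_s/conductivity", "dissolvr_bad_trace")
  meta_cols <- setdiff(names(df), need)
  lapply(split(df, df$run_id), function(run) {
    id <- run$run_id[1L]
    if (anyDuplicated(run$time_s))
      stop_dissolvr(sprintf("duplicated timestamp in run '%s'", id),
                    "dissolvr_duplicate_time")
    run <- run[order(run$time_s), , drop = FALSE]
    md <- lapply(run[meta_cols], function(col) col[1L])
    md$run_id <- id
    conductivity_trace(run$time_s, run$conductivity, md)
  })
}

#' Moving-median smoothing of a trace
#'
#' Centered moving median; near the endpoints the window shrinks
#' symmetrically so the output has full length. `window = 1` is the
#' identity. The median removes isolated sensor spikes while preserving
#' monotone sections exactly, so it does not bias threshold-crossing times.
#'
#' @param trace a [conductivity_trace()].
#' @param window_samples odd window length >= 1.
#' @return a smoothed [conductivity_trace()].
#' @export
smooth_trace <- function(trace, window_samples = 1L) {
  stopifnot(inherits(trace, "conductivity_trace"))
  w <- as.integer(window_samples)
  if (w < 1L || w %% 2L == 0L)
    stop_dissolvr("smoothing window must be odd and >= 1", "dissolvr_bad_window")
  if (w == 1L) return(trace)
  v <- trace$values
  n <- length(v)
  half <- (w - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    stats::median(v[(i - h):(i + h)])
  }, numeric(1L))
  conductivity_trace(trace$times, sm, trace$metadata)
}

#' Per-run 0-100% normalization of a conductivity trace
#'
#' Different solvents have different baseline conductivities, so absolute
#' readouts are not comparable across runs. Each run is rescaled to percent
#' of its own range: `v' = 100 * (v - min) / (max - min)`, with the anchors
#' taken over the analysis window (the minimum approximates the
#' pre-addition baseline, the maximum the dissolved plateau).
#'
#' @param trace a [conductivity_trace()] (smooth first if desired).
#' @param window restrict anchor search and output to `times <= window`
#'   seconds (relative to the first sample); `NULL` = whole trace.
#' @param anchor_method `"minmax"` (default): anchors are the exact minimum
#'   and maximum of the (smoothed) trace. `"reference"`: robust anchors for
#'   noisy sensors — the baseline anchor is the median of the leading
#'   `baseline_frac` of samples (the pre-addition segment) and the plateau
#'   anchor the median of the trailing `plateau_frac`; extreme order
#'   statistics of a noisy trace are biased outward, which `"reference"`
#'   avoids. Normalized values are clipped to `[0, 100]`.
#' @param baseline_frac,plateau_frac leading/trailing sample fractions used
#'   by the `"reference"` anchors (defaults 0.05 and 0.1).
#' @return an object of class `normalized_trace` with fields `times`,
#'   `values` (percent), `anchors` (raw low/high) and `metadata`.
#' @export
normalize_trace <- function(trace, window = NULL,
                            anchor_method = c("minmax", "reference"),
                            baseline_frac = 0.05, plateau_frac = 0.1) {
  stopifnot(inherits(trace, "conductivity_trace"))
  anchor_method <- match.arg(anchor_method)
  keep <- if (is.null(window)) rep(TRUE, length(trace$times))
          else trace$times <= trace$times[1L] + window
  if (sum(keep) < 2L)
    stop_dissolvr("analysis window contains fewer than 2 samples",
                  "dissolvr_bad_window")
  v <- trace$values[keep]
  if (anchor_method == "minmax") {
    lo <- min(v); hi <- max(v)
  } else {
    n <- length(v)
    lo <- stats::median(v[seq_len(max(1L, floor(baseline_frac * n)))])
    hi <- stats::median(v[(n - max(1L, floor(plateau_frac * n)) + 1L):n])
  }
  if (hi <= lo)
    stop_dissolvr("constant trace: no conductivity signal to normalize",
                  "dissolvr_no_signal")
  structure(
    list(times = trace$times[keep],
         values = pmin(100, pmax(0, 100 * (v - lo) / (hi - lo))),
         anchors = c(raw_lo = lo, raw_hi = hi), metadata = trace$metadata),
    class = "normalized_trace"
  )
}

#' Dissolution time t90 from a normalized trace
#'
#' The dissolution time is the time of the first sample at or above `level`
#' percent of the per-run range (default 90%), searched inside the
#' experimental window (default 60 s from the first sample). If no sample
#' reaches the level inside the window the run is flagged incomplete and
#' carries the window length as its censoring time — incomplete is a valid
#' result, not an error.
#'
#' @param ntrace a [normalized_trace()].
#' @param level percent threshold, default 90.
#' @param window observation window in seconds, default 60.
#' @return an object of class `dissolution_result` with fields `t90`,
#'   `incomplete`, `level`, `window`, `metadata`.
#' @export
dissolution_time <- function(ntrace, level = 90, window = 60) {
  stopifnot(inherits(ntrace, "normalized_trace"), level > 0, level <= 100,
            window > 0)
  t_rel <- ntrace$times - ntrace$times[1L]
  inside <- t_rel <= window
  idx <- first_crossing_index(ifelse(inside, ntrace$values, -Inf), level)
  incomplete <- is.na(idx)
  structure(
    list(t90 = if (incomplete) NA_real_ else t_rel[idx],
         censor_time = if (incomplete) window else NA_real_,
         incomplete = incomplete, level = level, window = window,
         metadata = ntrace$metadata),
    class = "dissolution_result"
  )
}

#' @export
print.dissolution_result <- function(x, ...) {
  if (x$incomplete)
    cat(sprintf("<dissolution_result> incomplete within %g s window [run %s]\n",
                x$window, x$metadata$run_id %||% "?"))
  else
    cat(sprintf("<dissolution_result> t90 = %.4f s [run %s]\n",
                x$t90, x$metadata$run_id %||% "?"))
  invisible(x)
}

#' Batch dissolution analysis with per-condition summaries
#'
#' Runs [smooth_trace()] + [normalize_trace()] + [dissolution_time()] on
#' every trace, then groups replicates by the metadata columns in `by` and
#' reports mean and sample SD of t90 per condition. Incomplete runs are
#' counted separately and never averaged: a condition's mean covers its
#' complete replicates only, with the incomplete count alongside.
#'
#' @param traces list of [conductivity_trace()] objects.
#' @param level,window passed to [dissolution_time()].
#' @param smooth odd moving-median window, default 1 (off).
#' @param anchor_method passed to [normalize_trace()]; use `"reference"`
#'   together with smoothing for noisy sensors.
#' @param by metadata fields defining a condition; defaults to every field
#'   except `run_id`.
#' @return list with `runs` (per-run results, a data.frame) and `summary`
#'   (per-condition data.frame: n_complete, n_incomplete, mean_t90_s,
#'   sd_t90_s).
#' @export
batch_dissolution <- function(traces, level = 90, window = 60, smooth = 1L,
                              anchor_method = "minmax", by = NULL) {
  stopifnot(length(traces) >= 1L)
  # anchors from the whole recorded trace (the dissolved plateau), not the
  # observation window: a run whose plateau lies beyond the window must be
  # flagged incomplete, not renormalized into completeness
  results <- lapply(traces, function(tr) {
    dissolution_time(
      normalize_trace(smooth_trace(tr, smooth), anchor_method = anchor_method),
      level = level, window = window
    )
  })
  meta_names <- unique(unlist(lapply(results, function(r) names(r$metadata))))
  by <- by %||% setdiff(meta_names, "run_id")
  runs <- do.call(rbind, lapply(results, function(r) {
    md <- r$metadata
    row <- data.frame(run_id = as.character(md$run_id %||% NA),
                      t90_s = r$t90, incomplete = r$incomplete,
                      stringsAsFactors = FALSE)
    for (f in by) row[[f]] <- if (is.null(md[[f]])) NA else md[[f]]
    row
  }))
  rownames(runs) <- NULL
  if (length(by) > 0L) {
    key <- interaction(runs[by], drop = TRUE, lex.order = TRUE)
  } else {
    key <- factor(rep("all", nrow(runs)))
  }
  summary <- do.call(rbind, lapply(split(runs, key), function(g) {
    ok <- !g$incomplete
    out <- g[1L, by, drop = FALSE]
    out$n_complete <- sum(ok)
    out$n_incomplete <- sum(!ok)
    out$mean_t90_s <- if (any(ok)) mean(g$t90_s[ok]) else NA_real_
    out$sd_t90_s <- if (sum(ok) >= 2L) stats::sd(g$t90_s[ok]) else NA_real_
    out
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}
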