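#' Specification of a synthetic discoloration video
#'
#' The generator emulates the decolorization assay: every pixel brightens
#' monotonically from a dark initial value `R0` (deep blue) toward a light
#' asymptote `R_inf` (colorless) along an exponential approach
#' `R(t) = R_inf - (R_inf - R0) * exp(-k(x, y) * t)`,
#' with the local mixing rate decaying with distance from the rotor center,
#' `k(x, y) = k0 * exp(-d / lambda)` — fast discoloration above the
#' impeller, slower toward the vessel wall. i.i.d. Gaussian gray noise and
#' 8-bit quantization can be added on top. The exponential surrogate is
#' chosen for its closed-form threshold-crossing times, which make the whole
#' analysis pipeline verifiable; it does not claim fluid-dynamic fidelity.
#'
#' Defaults mimic the scale of the laboratory assay: a region of interest of
#' 64 x 64 px filmed at 60 fps for 10 s, with rates giving 90%-mixed times
#' around one second.
#'
#' @param height,width frame size in pixels.
#' @param duration video length, seconds.
#' @param fps frame rate, default 60.
#' @param R0,R_inf initial and asymptotic gray levels, `0 <= R0 < R_inf <= 255`.
#' @param k0 base mixing rate at the rotor center, 1/s.
#' @param lambda spatial decay length of the rate field, pixels.
#' @param center rotor center `(row, col)`, 0-based; default frame center.
#' @param noise_sd gray-level SD of additive Gaussian noise; when > 0 the
#'   frames are also quantized to whole gray levels (8-bit camera model).
#'   `noise_sd = 0` keeps exact model values so analytic oracles match
#'   to double precision.
#' @param rgb render frames through the blue-to-colorless colormap of
#'   [render_rgb()] instead of grayscale.
#' @param seed RNG seed for the noise, default 1.
#' @return an object of class `video_synth_spec`.
#' @export
video_synth_spec <- function(height = 64L, width = 64L, duration = 10,
                             fps = 60, R0 = 40, R_inf = 240, k0 = 2,
                             lambda = 48, center = NULL, noise_sd = 0,
                             rgb = FALSE, seed = 1L) {
  center <- center %||% c((height - 1) / 2, (width - 1) / 2)
  spec <- list(height = as.integer(height), width = as.integer(width),
               duration = duration, fps = fps, R0 = R0, R_inf = R_inf,
               k0 = k0, lambda = lambda, center = center,
               noise_sd = noise_sd, rgb = isTRUE(rgb), seed = seed)
  if (!(R0 >= 0 && R0 < R_inf && R_inf <= 255))
    stop_dissolvr("need 0 <= R0 < R_inf <= 255", "dissolvr_bad_spec")
  if (k0 <= 0 || lambda <= 0 || fps <= 0 || duration <= 0 || noise_sd < 0)
    stop_dissolvr("k0, lambda, fps, duration must be > 0; noise_sd >= 0",
                  "dissolvr_bad_spec")
  if (height < 1L || width < 1L || duration * fps < 2)
    stop_dissolvr("need at least 2 frames", "dissolvr_bad_spec")
  structure(spec, class = "video_synth_spec")
}

rate_field <- function(spec) {
  rows <- matrix(0:(spec$height - 1L), spec$height, spec$width)
  cols <- matrix(0:(spec$width - 1L), spec$height, spec$width, byrow = TRUE)
  d <- sqrt((rows - spec$center[1L])^2 + (cols - spec$center[2L])^2)
  spec$k0 * exp(-d / spec$lambda)
}

#' Generate a synthetic discoloration video with ground truth
#'
#' @param spec a [video_synth_spec()].
#' @param X mixing coefficient assumed for the ground-truth crossing maps,
#'   default 0.5.
#' @param static_epsilon validity threshold assumed for the ground truth,
#'   matching the analysis default (10 gray levels).
#' @param mixed_level percent level for the ground-truth t90, default 90.
#' @return list with
#' * `stack`: the [frame_stack()] (or an `rgb_stack` when `spec$rgb`),
#' * `truth`: the `video_ground_truth`, holding the rate map `k`; the
#'   ideal closed-form crossing map `crossing = log(1 / (1 - X)) / k`; the
#'   `crossing_windowed` map, which additionally accounts for the analysis
#'   taking its fully-mixed reference from the last *observed* frame rather
#'   than the true asymptote (the two coincide once `k * duration` is
#'   large); the model-based validity mask; the continuous `t90`
#'   (level-percentile of crossing times over valid pixels) and `t90_grid`,
#'   its value snapped up to the frame grid — the exact value a noiseless
#'   pipeline run reports.
#' @export
synth_video <- function(spec, X = 0.5, static_epsilon = 10, mixed_level = 90) {
  stopifnot(inherits(spec, "video_synth_spec"), X >= 0, X < 1)
  k <- rate_field(spec)
  n_frames <- as.integer(floor(spec$duration * spec$fps))
  times <- (seq_len(n_frames) - 1L) / spec$fps
  amp <- spec$R_inf - spec$R0
  npx <- spec$height * spec$width
  frames <- array(0, dim = c(spec$height, spec$width, n_frames))
  kv <- c(k)
  for (i in seq_len(n_frames))
    frames[, , i] <- spec$R_inf - amp * exp(-kv * times[i])
  if (spec$noise_sd > 0) {
    frames <- with_seed(spec$seed, {
      frames + stats::rnorm(length(frames), sd = spec$noise_sd)
    })
    frames <- round_half_up(pmin(pmax(frames, 0), 255))
  }
  t_last <- times[n_frames]
  # validity as the analysis will see it: total change across the video
  valid <- amp * (1 - exp(-k * t_last)) >= static_epsilon
  crossing <- log(1 / (1 - X)) / k
  crossing_windowed <- -log(1 - X * (1 - exp(-k * t_last))) / k
  # continuous t90 from the ideal map (the model's definition); grid t90 from
  # the windowed map (the exact value a noiseless analysis run reports)
  q_ideal <- ground_truth_t90(crossing, valid, mixed_level, spec$fps, n_frames)
  truth <- ground_truth_t90(crossing_windowed, valid, mixed_level, spec$fps,
                            n_frames)
  truth$t90 <- q_ideal$t90
  gt <- structure(
    list(k = k, crossing = crossing, crossing_windowed = crossing_windowed,
         valid = valid, t90 = truth$t90, t90_grid = truth$t90_grid,
         censored = truth$censored, X = X, mixed_level = mixed_level,
         static_epsilon = static_epsilon, spec = spec),
    class = "video_ground_truth"
  )
  stack <- frame_stack(frames, fps = spec$fps)
  if (spec$rgb) stack <- render_rgb(stack)
  list(stack = stack, truth = gt)
}

# level-percentile of per-pixel crossing times, and its frame-grid value:
# the first frame time strictly greater than the percentile (strict because
# a pixel is mixed only strictly after its own crossing time)
ground_truth_t90 <- function(crossing, valid, level, fps, n_frames) {
  tv <- sort(crossing[valid])
  m <- ceiling(level / 100 * length(tv))
  q <- tv[m]
  k_star <- floor(q * fps) + 1  # 0-based frame index of first time > q
  censored <- k_star > n_frames - 1L
  list(t90 = q,
       t90_grid = if (censored) n_frames / fps else k_star / fps,
       censored = censored)
}

#' @export
print.video_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<video_ground_truth> t90 = %.4f s (grid %.4f s), %d/%d valid px, X = %g\n",
    x$t90, x$t90_grid, sum(x$valid), length(x$valid), x$X))
  invisible(x)
}

#' Render a grayscale stack through a blue-to-colorless colormap
#'
#' Monotone colormap emulating the starch-iodine decolorization: gray 0 maps
#' to saturated blue `(0, 0, 255)`, gray 255 to white `(255, 255, 255)`;
#' the red and green channels equal the gray value and blue is held at 255,
#' so the luma of the rendering is a strictly increasing function of the
#' input gray value.
#'
#' @param stack a grayscale [frame_stack()].
#' @return an `rgb_stack`: `H x W x 3 x T` array with `fps` / `t0_offset`
#'   attributes, convertible back with [to_grayscale()].
#' @export
render_rgb <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  out <- array(255, dim = c(d[1L], d[2L], 3L, d[3L]))
  out[, , 1L, ] <- stack$frames
  out[, , 2L, ] <- stack$frames
  structure(out, fps = stack$fps, t0_offset = stack$t0_offset,
            class = "rgb_stack")
}

#' Specification of a synthetic conductivity trace
#'
#' Emulates the conductometric dissolution signal: flat baseline until the
#' powder drop at `lag`, then a first-order rise
#' `v(t) = baseline + amplitude * (1 - exp(-(t - lag) / tau))`
#' with optional i.i.d. Gaussian noise. The 90% crossing of the normalized
#' trace has the closed form `t90 = lag + tau * log(10)`.
#'
#' @param tau first-order time constant, seconds.
#' @param baseline pre-addition conductivity, instrument units.
#' @param amplitude plateau rise above baseline, instrument units.
#' @param sample_rate Hz, default 100.
#' @param duration trace length, seconds; default `lag + 12 * tau` so the
#'   plateau is reached within double precision of the asymptote.
#' @param noise_sd noise SD as a fraction of `amplitude` (e.g. 0.01 = 1%).
#' @param lag seconds before powder addition, default 0.
#' @param seed RNG seed for the noise, default 1.
#' @return an object of class `trace_synth_spec`.
#' @export
trace_synth_spec <- function(tau, baseline = 50, amplitude = 450,
                             sample_rate = 100, duration = NULL,
                             noise_sd = 0, lag = 0, seed = 1L) {
  duration <- duration %||% (lag + 12 * tau)
  if (tau <= 0 || sample_rate <= 0 || duration <= tau || lag < 0 ||
      noise_sd < 0 || amplitude <= 0)
    stop_dissolvr("invalid trace spec (need tau > 0, duration > tau, ...)",
                  "dissolvr_bad_spec")
  structure(
    list(tau = tau, baseline = baseline, amplitude = amplitude,
         sample_rate = sample_rate, duration = duration, noise_sd = noise_sd,
         lag = lag, seed = seed),
    class = "trace_synth_spec"
  )
}

#' Generate a synthetic conductivity trace with known t90
#'
#' @param spec a [trace_synth_spec()].
#' @param metadata optional run metadata attached to the trace.
#' @return list with `trace` (a [conductivity_trace()]) and `true_t90`
#'   (`lag + tau * log(10)`, seconds).
#' @export
synth_trace <- function(spec, metadata = list()) {
  stopifnot(inherits(spec, "trace_synth_spec"))
  times <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  s <- pmax(0, times - spec$lag)
  v <- spec$baseline + spec$amplitude * (1 - exp(-s / spec$tau))
  if (spec$noise_sd > 0)
    v <- with_seed(spec$seed,
                   v + stats::rnorm(length(v), sd = spec$noise_sd * spec$amplitude))
  list(trace = conductivity_trace(times, v, metadata),
       true_t90 = spec$lag + spec$tau * log(10))
}

#' Generate a full-factorial design table with planted effects
#'
#' Builds the full factorial over the requested factor levels, replicated,
#' with response `grand_mean + main-effect shifts + interaction shifts +
#' N(0, residual_sd)`. Default levels mirror the multi-dose dissolution
#' study: rotor speed 150/225/300 rpm, Newtonian viscosity 0.89/1.60/3.90
#' mPa s, two particle-size classes, temperatures 5/25/45 degC.
#'
#' @param effects named list of main-effect shifts in seconds: one numeric
#'   vector per factor, named by level (unnamed levels shift 0).
#' @param interaction_effects named list, names like
#'   `"particle_class:viscosity_mPas"`, each a matrix of shifts with
#'   dimnames = the two factors' levels.
#' @param residual_sd residual noise SD, seconds.
#' @param replicates runs per cell, default 3 (the assay's triplicate).
#' @param levels named list of factor levels; see Details for defaults.
#' @param grand_mean baseline response, seconds; default 10.
#' @param seed RNG seed, default 1.
#' @return a `data.frame` design table (factors, `response_s`, `censored`),
#'   with the true model stored in attribute `truth`.
#' @export
synth_design <- function(effects = list(), interaction_effects = list(),
                         residual_sd = 1, replicates = 3L, levels = NULL,
                         grand_mean = 10, seed = 1L) {
  levels <- levels %||% list(
    rpm = c(150, 225, 300),
    viscosity_mPas = c(0.89, 1.60, 3.90),
    particle_class = c("<160um", "250-500um"),
    temp_C = c(5, 25, 45)
  )
  stopifnot(length(levels) >= 1L, replicates >= 1L, residual_sd >= 0)
  if (any(lengths(levels) < 2L))
    stop_dissolvr("every factor needs >= 2 levels", "dissolvr_bad_spec")
  bad <- setdiff(names(effects), names(levels))
  if (length(bad) > 0L)
    stop_dissolvr(sprintf("effects name unknown factor(s): %s",
                          paste(bad, collapse = ", ")), "dissolvr_bad_spec")
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- grid[rep(seq_len(nrow(grid)), each = replicates), , drop = FALSE]
  rownames(design) <- NULL
  mu <- rep(grand_mean, nrow(design))
  for (f in names(effects)) {
    shift <- effects[[f]]
    if (is.null(names(shift)))
      stop_dissolvr(sprintf("effect vector for '%s' must be named by level", f),
                    "dissolvr_bad_spec")
    hit <- match(as.character(design[[f]]), names(shift))
    mu <- mu + ifelse(is.na(hit), 0, shift[hit])
  }
  for (nm in names(interaction_effects)) {
    fs <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(fs) != 2L || !all(fs %in% names(levels)))
      stop_dissolvr(sprintf("bad interaction spec '%s'", nm), "dissolvr_bad_spec")
    m <- interaction_effects[[nm]]
    ia <- match(as.character(design[[fs[1L]]]), rownames(m))
    ib <- match(as.character(design[[fs[2L]]]), colnames(m))
    ok <- !is.na(ia) & !is.na(ib)
    mu[ok] <- mu[ok] + m[cbind(ia[ok], ib[ok])]
  }
  resp <- if (residual_sd > 0)
    with_seed(seed, mu + stats::rnorm(length(mu), sd = residual_sd))
  else mu
  design$response_s <- resp
  design$censored <- FALSE
  attr(design, "truth") <- list(grand_mean = grand_mean, effects = effects,
                                interaction_effects = interaction_effects,
                                residual_sd = residual_sd, mu = mu, seed = seed)
  design
}
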