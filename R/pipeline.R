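# Top-level pipeline runner and command-line entry point. One structured
# config per run, explicit seeds, and a manifest listing every artifact with
# its digest, so identical config + inputs reproduce identical outputs.

#' Run a configured analysis pipeline
#'
#' Executes one stage — `synth_video`, `synth_trace`, `synth_design`,
#' `colorimetry`, `conductometry`, `doe`, or the end-to-end `demo` — from a
#' declarative config, writes its artifacts under `out`, and returns a run
#' manifest. Configs are JSON files (or equivalent R lists) with fields
#' `stage`, `out`, optional `seed`, and a `params` block whose schema is
#' validated per stage; violations are reported with the offending field
#' path.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @param out output directory override.
#' @return the run manifest (invisibly written to `manifest.json`): stage,
#'   config digest, input digests, package version, seed, timestamp, and
#'   the output inventory with digests.
#' @export
run_pipeline <- function(config, out = NULL) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    if (!file.exists(cfg_path))
      stop_dissolvr(sprintf("config '%s' does not exist", cfg_path),
                    "dissolvr_missing_source")
    config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  stage <- config$stage %||% schema_fail("stage", "missing")
  stages <- c("synth_video", "synth_trace", "synth_design", "colorimetry",
              "conductometry", "doe", "demo")
  if (!stage %in% stages)
    schema_fail("stage", sprintf("must be one of %s", paste(stages, collapse = ", ")))
  out <- out %||% config$out %||% schema_fail("out", "missing")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- config$params %||% list()
  seed <- config$seed %||% 1L
  inputs <- character()

  outputs <- switch(stage,
    synth_video = stage_synth_video(params, seed, out),
    synth_trace = stage_synth_trace(params, seed, out),
    synth_design = stage_synth_design(params, seed, out),
    colorimetry = {
      inputs <- c(inputs, params$input %||% schema_fail("params.input", "missing"))
      stage_colorimetry(params, out)
    },
    conductometry = {
      inputs <- c(inputs, params$input %||% schema_fail("params.input", "missing"))
      stage_conductometry(params, out)
    },
    doe = {
      inputs <- c(inputs, params$design %||% schema_fail("params.design", "missing"))
      stage_doe(params, out)
    },
    demo = stage_demo(params, seed, out)
  )

  manifest <- list(
    stage = stage,
    config_digest = digest_obj(config),
    inputs = digest_files(inputs),
    package_version = as.character(utils::packageVersion("dissolvr")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = digest_files(outputs)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

schema_fail <- function(field, why) {
  stop_dissolvr(sprintf("config field '%s': %s", field, why),
                "dissolvr_config_schema")
}

digest_files <- function(paths) {
  if (length(paths) == 0L) return(stats::setNames(list(), character()))
  files <- normalizePath(unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  })))
  as.list(tools::md5sum(files))
}

digest_obj <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

check_level <- function(level, field) {
  if (!is.numeric(level) || level <= 0 || level > 100)
    schema_fail(field, "must be a percentage in (0, 100]")
  level
}

stage_synth_video <- function(params, seed, out) {
  spec_args <- params[intersect(names(params), names(formals(video_synth_spec)))]
  spec_args$seed <- spec_args$seed %||% seed
  spec <- do.call(video_synth_spec, spec_args)
  sv <- synth_video(spec,
                    X = params$x %||% 0.5,
                    static_epsilon = params$epsilon %||% 10,
                    mixed_level = check_level(params$level %||% 90, "params.level"))
  frame_dir <- file.path(out, "frames")
  paths <- write_frames(if (spec$rgb) to_grayscale(sv$stack) else sv$stack,
                        frame_dir)
  gt_path <- file.path(out, "ground_truth.json")
  jsonlite::write_json(
    list(t90_s = fmt_time(sv$truth$t90), t90_grid_s = fmt_time(sv$truth$t90_grid),
         censored = sv$truth$censored, X = sv$truth$X,
         n_valid = sum(sv$truth$valid),
         spec = unclass(spec)),
    gt_path, auto_unbox = TRUE, digits = NA
  )
  c(paths, gt_path)
}

stage_synth_trace <- function(params, seed, out) {
  specs <- params$traces %||% schema_fail("params.traces", "missing")
  if (is.data.frame(specs)) specs <- split(specs, seq_len(nrow(specs)))
  traces <- list()
  truth <- list()
  for (i in seq_along(specs)) {
    p <- as.list(specs[[i]])
    run_id <- p$run_id %||% sprintf("run%03d", i)
    spec_args <- p[intersect(names(p), names(formals(trace_synth_spec)))]
    spec_args$seed <- spec_args$seed %||% (derive_seed(seed, i))
    st <- synth_trace(do.call(trace_synth_spec, spec_args),
                      metadata = c(list(run_id = run_id),
                                   p[setdiff(names(p),
                                             c(names(spec_args), "run_id"))]))
    traces[[run_id]] <- st$trace
    truth[[run_id]] <- fmt_time(st$true_t90)
  }
  tp <- file.path(out, "traces.csv")
  write_traces(traces, tp)
  gt <- file.path(out, "trace_truth.json")
  jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA)
  c(tp, gt)
}

stage_synth_design <- function(params, seed, out) {
  args <- params[intersect(names(params), names(formals(synth_design)))]
  args$seed <- args$seed %||% seed
  design <- do.call(synth_design, args)
  dp <- file.path(out, "design.csv")
  write_design(design, dp)
  dp
}

stage_colorimetry <- function(params, out) {
  fps <- params$fps %||% schema_fail("params.fps", "missing")
  stack <- load_frames(params$input, fps = fps)
  cfg <- colorimetry_config(
    mixing_coefficient = params$x %||% 0.5,
    mixed_level = check_level(params$level %||% 90, "params.level"),
    static_epsilon = params$epsilon %||% 10,
    reference_last_n = params$reference_last_n %||% 1L
  )
  roi <- NULL
  if (!is.null(params$roi)) {
    r <- as.numeric(params$roi)
    if (length(r) != 4L) schema_fail("params.roi", "expected r0,c0,h,w")
    roi <- roi_rect(r[1L], r[2L], r[3L], r[4L])
  }
  an <- analyze_video(stack, cfg, roi = roi)
  digest <- digest_obj(lapply(digest_files(params$input), unname))
  p1 <- file.path(out, "mixing_curve.csv")
  p2 <- file.path(out, "discoloration_result.json")
  p3 <- file.path(out, "first_mixed_map.csv")
  write_mixing_curve(an$curve, p1)
  write_discoloration_json(an$result, p2, input_digest = digest)
  write_first_mixed_csv(an$first_mixed, p3)
  c(p1, p2, p3)
}

stage_conductometry <- function(params, out) {
  traces <- load_traces(params$input)
  level <- check_level(params$level %||% 90, "params.level")
  window <- params$window %||% 60
  if (!is.numeric(window) || window <= 0) schema_fail("params.window", "must be > 0")
  res <- batch_dissolution(traces, level = level, window = window,
                           smooth = params$smooth %||% 1L,
                           anchor_method = params$anchors %||% "minmax")
  p1 <- file.path(out, "dissolution_runs.csv")
  p2 <- file.path(out, "dissolution_summary.csv")
  runs <- res$runs
  runs$t90_s <- fmt_time(runs$t90_s)
  utils::write.csv(runs, p1, row.names = FALSE)
  summ <- res$summary
  summ$mean_t90_s <- fmt_time(summ$mean_t90_s)
  summ$sd_t90_s <- fmt_time(summ$sd_t90_s)
  utils::write.csv(summ, p2, row.names = FALSE)
  c(p1, p2)
}

stage_doe <- function(params, out) {
  design <- read_design(params$design)
  alpha <- params$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    schema_fail("params.alpha", "must be in (0, 1)")
  interactions <- params$interactions
  if (is.character(interactions) && length(interactions) == 1L)
    interactions <- strsplit(interactions, ",", fixed = TRUE)[[1L]]
  report <- factorial_effects(design,
                              response = params$response %||% "response_s",
                              factors = params$factors,
                              interactions = as.list(interactions),
                              alpha = alpha)
  p1 <- file.path(out, "effects_report.csv")
  write_effects_report(report, p1)
  p1
}

stage_demo <- function(params, seed, out) {
  # synthetic video -> colorimetry
  vdir <- file.path(out, "video")
  run_pipeline(list(stage = "synth_video", out = vdir, seed = seed,
                    params = params$video %||% list()))
  cdir <- file.path(out, "colorimetry")
  run_pipeline(list(stage = "colorimetry", out = cdir,
                    params = list(input = file.path(vdir, "frames"), fps = 60)))
  # synthetic traces -> conductometry
  tdir <- file.path(out, "traces")
  taus <- c(0.5, 1, 2)
  trace_specs <- do.call(rbind, lapply(seq_along(taus), function(i)
    data.frame(run_id = sprintf("tau%02d_r%d", rep(i, 3), 1:3),
               tau = taus[i], noise_sd = 0.01, lag = 1, solvent = "water",
               viscosity_mPas = 0.89, rpm = 300)))
  run_pipeline(list(stage = "synth_trace", out = tdir, seed = seed,
                    params = list(traces = trace_specs)))
  ddir <- file.path(out, "conductometry")
  run_pipeline(list(stage = "conductometry", out = ddir,
                    params = list(input = file.path(tdir, "traces.csv"),
                                  smooth = 5, anchors = "reference")))
  # synthetic design -> factorial screening
  gdir <- file.path(out, "design")
  run_pipeline(list(stage = "synth_design", out = gdir, seed = seed,
                    params = list(effects = list(viscosity_mPas = c("3.9" = 5)),
                                  residual_sd = 0.5)))
  edir <- file.path(out, "doe")
  run_pipeline(list(stage = "doe", out = edir,
                    params = list(design = file.path(gdir, "design.csv"))))
  unlist(lapply(c(vdir, cdir, tdir, ddir, gdir, edir), function(d)
    setdiff(list.files(d, full.names = TRUE, recursive = TRUE), character())))
}

#' Command-line entry point
#'
#' Dispatches `dissolvr <stage> [--flag value ...]`. Stages and flags:
#' * `colorimetry --input DIR --fps 60 [--roi r0,c0,h,w --x 0.5 --level 90
#'   --epsilon 10] --out DIR`
#' * `conductometry --input traces.csv [--level 90 --window 60 --smooth 1]
#'   --out DIR`
#' * `doe --design design.csv [--alpha 0.05 --interactions a:b,c:d] --out DIR`
#' * `synth_video | synth_trace | synth_design | demo [--seed N] --config
#'   spec.json --out DIR`
#' * `run --config config.json [--out DIR]` (stage taken from the config)
#'
#' The installed launcher script lives at
#' `system.file("cli", "dissolvr", package = "dissolvr")`.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return the run manifest, invisibly.
#' @export
dissolvr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop_dissolvr("usage: dissolvr <stage> [--flag value ...]; see ?dissolvr_cli",
                  "dissolvr_config_schema")
  stage <- args[[1L]]
  flags <- parse_flags(args[-1L])
  if (!is.null(flags$config)) {
    config <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    if (stage != "run") config$stage <- stage
    if (!is.null(flags$out)) config$out <- flags$out
    if (!is.null(flags$seed)) config$seed <- as.integer(flags$seed)
    return(run_pipeline(config))
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  params <- switch(stage,
    colorimetry = list(input = flags$input, fps = num(flags$fps),
                       x = num(flags$x), level = num(flags$level),
                       epsilon = num(flags$epsilon),
                       roi = if (!is.null(flags$roi))
                         as.numeric(strsplit(flags$roi, ",")[[1L]])),
    conductometry = list(input = flags$input, level = num(flags$level),
                         window = num(flags$window), smooth = num(flags$smooth)),
    doe = list(design = flags$design, alpha = num(flags$alpha),
               interactions = flags$interactions),
    schema_fail("config", sprintf("stage '%s' needs --config", stage))
  )
  params <- params[!vapply(params, is.null, logical(1L))]
  run_pipeline(list(stage = stage, out = flags$out, params = params,
                    seed = if (!is.null(flags$seed)) as.integer(flags$seed)))
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--") || i == length(args))
      stop_dissolvr(sprintf("malformed argument '%s'", a), "dissolvr_config_schema")
    flags[[substring(a, 3L)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}
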