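#' Per-group mean and standard deviation
#'
#' @param groups named list of numeric replicate vectors (e.g. t90 values in
#'   seconds per rotor geometry), or a data.frame with columns `group` and
#'   `value`.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`; the sample SD
#'   (n - 1 denominator) is `NA` for singleton groups.
#' @export
group_summary <- function(groups) {
  groups <- as_group_list(groups)
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1L)),
    mean = vapply(groups, mean, numeric(1L)),
    sd = vapply(groups, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_,
                numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(is.list(groups), length(groups) >= 1L,
            all(vapply(groups, is.numeric, logical(1L))),
            all(vapply(groups, length, integer(1L)) >= 1L))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA across groups followed by Tukey's honestly
#' significant difference procedure, controlling the family-wise error rate
#' at `alpha` over all pairwise comparisons. Equality of variances is an
#' (untested) model assumption, as in the classical procedure.
#'
#' @param groups as in [group_summary()]; >= 2 groups, each n >= 2.
#' @param alpha family-wise significance level, default 0.05.
#' @return list with `F`, `df1`, `df2`, `p`, `significant` (omnibus), and
#'   `tukey`: a data.frame of pairwise contrasts (`diff`, `lwr`, `upr`,
#'   `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L)
    stop_dissolvr("need >= 2 groups", "dissolvr_bad_groups")
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop_dissolvr("every group needs n >= 2 for variance-based tests",
                  "dissolvr_bad_groups")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  fstat <- tab[["F value"]][1L]
  pval <- tab[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(
    contrast = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE
  )
  rownames(tukey) <- NULL
  list(F = fstat, df1 = as.integer(tab[["Df"]][1L]),
       df2 = as.integer(tab[["Df"]][2L]), p = pval,
       significant = is.finite(pval) && pval < alpha, alpha = alpha,
       tukey = tukey)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sample t-test. Degenerate inputs with zero
#' pooled variance are handled by convention: equal means give `t = 0,
#' p = 1`; unequal means with zero variance are reported as infinitely
#' significant (`p = 0`), since any difference is then exact.
#'
#' @param a,b numeric replicate vectors, each n >= 2.
#' @param two_sided default `TRUE`.
#' @return list with `t`, `dof`, `p`, `mean_a`, `mean_b`.
#' @export
ttest_two_sample <- function(a, b, two_sided = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  dof <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / dof
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    tt <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    res <- stats::t.test(a, b, var.equal = TRUE,
                         alternative = if (two_sided) "two.sided" else "greater")
    tt <- unname(res$statistic)
    p <- res$p.value
  }
  list(t = tt, dof = dof, p = p, mean_a = mean(a), mean_b = mean(b))
}

#' Full-factorial effect and interaction screening
#'
#' Fits a fixed-effects linear model with all requested main effects plus
#' the named two-way interactions, all factors categorically coded, and
#' reports per-term F tests from the sequential ANOVA table (for the
#' balanced full factorials this package generates, sequential and marginal
#' tests coincide). Censored (incomplete-dissolution) runs are excluded
#' before fitting, with the count reported.
#'
#' @param design data.frame of runs: factor columns plus a numeric response.
#'   A logical `censored` column, if present, drops those runs.
#' @param response name of the response column, default `"response_s"`.
#' @param factors character vector of factor column names; default: every
#'   column except the response and `censored`.
#' @param interactions list of length-2 character vectors (or
#'   `"a:b"` strings) naming two-way interactions to include; default the
#'   particle-size x viscosity and rotor-speed x viscosity pairs when those
#'   columns exist, else none.
#' @param alpha significance level for flagging, default 0.05.
#' @return an `effects_report`: data.frame with columns `term`, `df`,
#'   `sum_sq`, `F`, `df_resid`, `p`, `significant`; attributes carry the
#'   fitted model and the number of censored runs excluded.
#' @export
factorial_effects <- function(design, response = "response_s", factors = NULL,
                              interactions = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(design), response %in% names(design))
  n_censored <- 0L
  if ("censored" %in% names(design)) {
    cen <- as.logical(design$censored)
    n_censored <- sum(cen)
    if (n_censored > 0L)
      message(sprintf("excluding %d censored run(s) from the factorial model",
                      n_censored))
    design <- design[!cen, , drop = FALSE]
  }
  factors <- factors %||% setdiff(names(design), c(response, "censored"))
  missing_f <- setdiff(factors, names(design))
  if (length(missing_f) > 0L)
    stop_dissolvr(sprintf("unknown factor column(s): %s",
                          paste(missing_f, collapse = ", ")),
                  "dissolvr_unknown_factor")
  if (is.null(interactions)) {
    interactions <- list()
    if (all(c("particle_class", "viscosity_mPas") %in% factors))
      interactions <- c(interactions, list(c("particle_class", "viscosity_mPas")))
    if (all(c("rpm", "viscosity_mPas") %in% factors))
      interactions <- c(interactions, list(c("rpm", "viscosity_mPas")))
  }
  interactions <- lapply(interactions, function(x) {
    if (length(x) == 1L) x <- strsplit(x, ":", fixed = TRUE)[[1L]]
    stopifnot(length(x) == 2L, all(x %in% factors))
    x
  })
  mdata <- design[c(response, factors)]
  for (f in factors) mdata[[f]] <- factor(mdata[[f]])
  empty <- factors[vapply(mdata[factors], nlevels, integer(1L)) < 2L]
  if (length(empty) > 0L)
    stop_dissolvr(sprintf("factor(s) with < 2 observed levels: %s",
                          paste(empty, collapse = ", ")),
                  "dissolvr_aliased_term")
  terms <- c(factors, vapply(interactions, paste, character(1L), collapse = ":"))
  fml <- stats::reformulate(terms, response = response)
  fit <- stats::lm(fml, data = mdata)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_dissolvr(sprintf("aliased/empty design cells; inestimable: %s",
                          paste(bad, collapse = ", ")),
                  "dissolvr_aliased_term")
  }
  if (stats::df.residual(fit) < 1L)
    stop_dissolvr("no residual degrees of freedom: add replicates or drop terms",
                  "dissolvr_no_residual_df")
  # a zero-residual-variance fit (e.g. exactly constant response) is a
  # documented edge case: its NaN F values are reported as not significant
  at <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  k <- nrow(at) - 1L
  rep_df <- data.frame(
    term = rownames(at)[seq_len(k)],
    df = at$Df[seq_len(k)],
    sum_sq = at$`Sum Sq`[seq_len(k)],
    F = at$`F value`[seq_len(k)],
    df_resid = at$Df[k + 1L],
    p = at$`Pr(>F)`[seq_len(k)],
    stringsAsFactors = FALSE
  )
  # zero residual variance (e.g. an exactly constant response) gives NaN F
  rep_df$significant <- !is.na(rep_df$p) & rep_df$p < alpha
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("effects_report", "data.frame"),
            alpha = alpha, n_censored = n_censored, model = fit)
}

#' Cell-mean response matrix for two factors
#'
#' Mean response for every level pair of two factors, marginalized over all
#' remaining factors and replicates — the numbers behind a response-surface
#' heat map. Empty cells are `NA`, never zero-filled.
#'
#' @param design data.frame of runs (censored runs excluded as in
#'   [factorial_effects()]).
#' @param factor_a,factor_b column names; `factor_a` indexes rows.
#' @param response response column name, default `"response_s"`.
#' @return numeric matrix, `dimnames` = sorted factor levels.
#' @export
cell_mean_matrix <- function(design, factor_a, factor_b,
                             response = "response_s") {
  stopifnot(is.data.frame(design))
  for (f in c(factor_a, factor_b, response))
    if (!f %in% names(design))
      stop_dissolvr(sprintf("unknown column '%s'", f), "dissolvr_unknown_factor")
  if ("censored" %in% names(design))
    design <- design[!as.logical(design$censored), , drop = FALSE]
  tapply(design[[response]],
         list(factor(design[[factor_a]]), factor(design[[factor_b]])),
         mean)
}

#' Rotor-speed multiplier for constant impeller Reynolds number
#'
#' The impeller Reynolds number `Re = rho * N * D^2 / mu` is the standard
#' similarity group for stirred-vessel scale-up. At fixed fluid properties,
#' holding Re constant while the impeller diameter changes by
#' `diameter_ratio` requires the rotational speed to change by
#' `diameter_ratio^2`: scaling a 1 cm reconstitution chamber up four-fold
#' in diameter therefore demands a 16-fold rotor-speed increase.
#'
#' @param diameter_ratio D_large / D_small, > 0.
#' @return the rotor-speed multiplier `diameter_ratio^2`.
#' @export
reynolds_speed_factor <- function(diameter_ratio) {
  if (!is.numeric(diameter_ratio) || any(diameter_ratio <= 0))
    stop_dissolvr("diameter_ratio must be > 0", "dissolvr_bad_ratio")
  diameter_ratio^2
}
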