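test_that("group_summary reports mean and sample SD per group", {
  out <- group_summary(list(a = c(1, 2, 3), b = rep(4, 5), c = 7))
  expect_equal(out$mean, c(2, 4, 7))
  expect_equal(out$sd[1:2], c(1, 0))
  expect_true(is.na(out$sd[3]))  # singleton: SD undefined, not 0
  expect_equal(out$n, c(3L, 5L, 1L))
  # data.frame interface
  df <- data.frame(group = rep(c("x", "y"), each = 3), value = c(1, 2, 3, 4, 5, 6))
  expect_equal(group_summary(df)$mean, c(2, 5))
})

test_that("anova_tukey matches brute-force sums of squares and ptukey", {
  set.seed(101)
  fixtures <- list(
    list(a = rnorm(5, 1.9, 0.12), b = rnorm(5, 2.4, 0.17), c = rnorm(5, 3.2, 0.17)),
    list(g1 = rnorm(4, 10), g2 = rnorm(6, 10.5), g3 = rnorm(5, 12), g4 = rnorm(5, 10)),
    list(u = runif(8), v = runif(8), w = runif(8))
  )
  for (groups in fixtures) {
    got <- anova_tukey(groups)
    ora <- oracle_anova(groups)
    expect_equal(got$F, ora$F, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
    expect_identical(c(got$df1, got$df2), c(ora$df1, ora$df2))
    tk <- oracle_tukey_p(groups)
    expect_equal(sort(got$tukey$p_adj), sort(unname(tk)), tolerance = 1e-6)
  }
})

test_that("a separated middle group is flagged against both neighbors", {
  set.seed(7)
  jitter <- function(x) x + rnorm(5, sd = 1e-3)
  groups <- list(lo = jitter(rep(0, 5)), hi = jitter(rep(10, 5)),
                 lo2 = jitter(rep(0, 5)))
  res <- anova_tukey(groups)
  expect_true(res$significant)
  sig <- res$tukey$significant
  names(sig) <- res$tukey$contrast
  expect_true(sig[["hi-lo"]])
  expect_true(sig[["lo2-hi"]])
  expect_false(sig[["lo2-lo"]])
  # identical groups: F = 0, nothing significant
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res0 <- anova_tukey(same)
  expect_equal(res0$F, 0)
  expect_false(any(res0$tukey$significant))
  expect_error(anova_tukey(list(a = 1:3)), class = "dissolvr_bad_groups")
  expect_error(anova_tukey(list(a = 1:3, b = 5)), class = "dissolvr_bad_groups")
})

test_that("pooled t-test matches the hand formula and handles degeneracy", {
  a <- c(9.1, 9.2, 9.0); b <- c(1.5, 1.4, 1.6)  # the two-salt comparison shape
  got <- ttest_two_sample(a, b)
  ora <- oracle_pooled_t(a, b)
  expect_equal(got$t, ora$t, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  expect_identical(got$dof, 4L)
  expect_lt(got$p, 0.05)
  # identical groups
  same <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero pooled variance conventions
  expect_equal(ttest_two_sample(c(2, 2), c(2, 2))$p, 1)
  expect_equal(ttest_two_sample(c(3, 3), c(2, 2))$p, 0)
})

test_that("two-group one-way ANOVA F equals t squared", {
  set.seed(21)
  for (i in 1:5) {
    a <- rnorm(5, 2, 0.3); b <- rnorm(4, 2.5, 0.3)
    f <- anova_tukey(list(a = a, b = b))$F
    t <- ttest_two_sample(a, b)$t
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("factorial_effects recovers planted main effects and interactions", {
  # planted viscosity shift of 5 s at sigma = 0.1: only viscosity significant
  d <- synth_design(effects = list(viscosity_mPas = c("3.9" = 5)),
                    residual_sd = 0.1, seed = 5)
  rep1 <- factorial_effects(d)
  sig <- setNames(rep1$significant, rep1$term)
  expect_true(sig[["viscosity_mPas"]])
  expect_false(any(sig[setdiff(names(sig), "viscosity_mPas")]))
  # planted pure interaction: effect only for fine particles in thick solvent
  ie <- matrix(0, 2, 3, dimnames = list(c("<160um", "250-500um"),
                                        c("0.89", "1.6", "3.9")))
  ie["<160um", "3.9"] <- 5
  d2 <- synth_design(interaction_effects = list("particle_class:viscosity_mPas" = ie),
                     residual_sd = 0.1, seed = 6)
  rep2 <- factorial_effects(d2)
  ia_term <- grep("particle_class", grep("viscosity", rep2$term, value = TRUE),
                  value = TRUE)
  expect_length(ia_term, 1)
  expect_true(rep2$significant[rep2$term == ia_term])
  # all-constant response: residual variance 0, no term significant
  d3 <- synth_design(residual_sd = 0)
  rep3 <- factorial_effects(d3)
  expect_false(any(rep3$significant))
})

test_that("factorial_effects excludes censored runs and validates inputs", {
  d <- synth_design(effects = list(rpm = c("150" = 3)), residual_sd = 0.2, seed = 9)
  d$censored[1:5] <- TRUE
  expect_message(rep1 <- factorial_effects(d), "5 censored")
  expect_equal(attr(rep1, "n_censored"), 5L)
  expect_true(rep1$significant[rep1$term == "rpm"])
  expect_error(factorial_effects(d, factors = c("rpm", "nope")),
               class = "dissolvr_unknown_factor")
  # a factor collapsed to one observed level is reported, not dropped silently
  d4 <- d[d$particle_class == "<160um", ]
  expect_error(factorial_effects(d4), class = "dissolvr_aliased_term")
})

test_that("factorial term tests hold their type-I error under the null", {
  # 2^3 design, 3 replicates, pure noise; nominal alpha = 0.05
  lv <- list(rpm = c(150, 300), viscosity_mPas = c(0.89, 3.90),
             particle_class = c("<160um", "250-500um"))
  n_rep <- 400L
  hits <- 0L
  for (i in seq_len(n_rep)) {
    d <- synth_design(residual_sd = 1, replicates = 3, levels = lv,
                      seed = 5000 + i)
    rep_i <- factorial_effects(d, interactions = list())
    hits <- hits + sum(rep_i$significant)
  }
  rate <- hits / (n_rep * 3L)  # 3 main-effect terms per rep
  expect_gt(rate, 0.05 - 0.02)
  expect_lt(rate, 0.05 + 0.02)
})

test_that("cell_mean_matrix marginalizes and marks empty cells", {
  d <- data.frame(a = rep(c("a1", "a2"), each = 2), b = rep(c("b1", "b2"), 2),
                  response_s = c(1, 2, 3, 4))
  m <- cell_mean_matrix(d, "a", "b")
  expect_equal(unname(m), matrix(c(1, 3, 2, 4), 2, 2))
  # replicate averaging
  d2 <- rbind(d, data.frame(a = "a1", b = "b1", response_s = 3))
  expect_equal(cell_mean_matrix(d2, "a", "b")["a1", "b1"], 2)
  # empty cell -> NA marker
  d3 <- d[-1, ]
  expect_true(is.na(cell_mean_matrix(d3, "a", "b")["a1", "b1"]))
  expect_error(cell_mean_matrix(d, "a", "zz"), class = "dissolvr_unknown_factor")
})

test_that("reynolds_speed_factor follows the square law", {
  expect_identical(reynolds_speed_factor(4), 16)
  expect_identical(reynolds_speed_factor(1), 1)
  expect_identical(reynolds_speed_factor(2), 4)
  # multiplicativity f(ab) = f(a) f(b)
  for (pair in list(c(2, 3), c(1.5, 4), c(0.5, 8))) {
    expect_equal(reynolds_speed_factor(pair[1] * pair[2]),
                 reynolds_speed_factor(pair[1]) * reynolds_speed_factor(pair[2]))
  }
  expect_error(reynolds_speed_factor(0), class = "dissolvr_bad_ratio")
  expect_error(reynolds_speed_factor(-2), class = "dissolvr_bad_ratio")
})

test_that("planted effects of >= 3 residual SDs are detected with high power", {
  # paper-scale replication (n = 3), effect 3 sigma: power > 0.9
  lv <- list(rpm = c(150, 225, 300), viscosity_mPas = c(0.89, 1.60, 3.90))
  hits <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    d <- synth_design(effects = list(viscosity_mPas = c("3.9" = 3)),
                      residual_sd = 1, replicates = 3, levels = lv,
                      seed = 800 + i)
    rep_i <- factorial_effects(d, interactions = list())
    hits <- hits + rep_i$significant[rep_i$term == "viscosity_mPas"]
  }
  expect_gt(hits / n_rep, 0.9)
})
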