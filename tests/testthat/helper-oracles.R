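# Independent brute-force oracles, deliberately written as plain scalar
# loops / textbook formulas so they share no code path with the package.

# Direct double-loop evaluation of the per-pixel threshold rule and the
# mixed-pixel ratio on a raw H x W x T gray array.
oracle_mixing_curve <- function(frames, X = 0.5, eps = 10, strict = TRUE,
                                ref_last_n = 1L) {
  d <- dim(frames)
  H <- d[1L]; W <- d[2L]; TT <- d[3L]
  beta <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      r0 <- frames[i, j, 1L]
      rinf <- mean(frames[i, j, (TT - ref_last_n + 1L):TT])
      beta[i, j] <- r0 + X * (rinf - r0)
      valid[i, j] <- abs(rinf - r0) >= eps
    }
  }
  nv <- sum(valid)
  M <- numeric(TT)
  for (k in seq_len(TT)) {
    cnt <- 0L
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (!valid[i, j]) next
        v <- frames[i, j, k]
        hit <- if (strict) v > beta[i, j] else v >= beta[i, j]
        if (hit) cnt <- cnt + 1L
      }
    }
    M[k] <- 100 * cnt / nv
  }
  list(M = M, n_valid = nv, beta = beta, valid = valid)
}

# One-way fixed-effects ANOVA from explicit sums of squares.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                           numeric(1L)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df1 <- length(groups) - 1L
  df2 <- length(all_v) - length(groups)
  Fv <- (ss_between / df1) / (ss_within / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

# Tukey HSD adjusted p-values from the studentized range distribution.
oracle_tukey_p <- function(groups) {
  k <- length(groups)
  df2 <- length(unlist(groups)) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L))) / df2
  out <- c()
  nms <- names(groups)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt(mse / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
      q <- abs(mean(groups[[j]]) - mean(groups[[i]])) / se
      out[paste(nms[j], nms[i], sep = "-")] <-
        stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }
  }
  out
}

# Classical pooled two-sample t by hand.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, dof = na + nb - 2,
       p = 2 * stats::pt(abs(tt), na + nb - 2, lower.tail = FALSE))
}

# Random 8-bit gray stack with a sprinkle of static pixels, for the
# equation-oracle equivalence checks.
random_gray_stack <- function(seed, H = 16L, W = 16L, TT = 50L,
                              static_frac = 0.1) {
  set.seed(seed)
  frames <- array(sample(0:255, H * W * TT, replace = TRUE), dim = c(H, W, TT))
  n_static <- round(static_frac * H * W)
  if (n_static > 0L) {
    idx <- sample(H * W, n_static)
    lvl <- sample(0:255, n_static, replace = TRUE)
    for (s in seq_len(n_static)) {
      i <- (idx[s] - 1L) %% H + 1L
      j <- (idx[s] - 1L) %/% H + 1L
      frames[i, j, ] <- lvl[s]
    }
  }
  frames
}

# Monotone non-decreasing random stack (each pixel a sorted random walk).
monotone_gray_stack <- function(seed, H = 8L, W = 8L, TT = 40L) {
  set.seed(seed)
  frames <- array(0, dim = c(H, W, TT))
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      start <- stats::runif(1, 0, 80)
      gain <- stats::runif(1, 0, 170)
      frames[i, j, ] <- start + gain * sort(stats::runif(TT))
    }
  }
  frames
}

# Spec distribution for the closed-form video recovery criteria: rate
# fields with k * duration >= ~14 everywhere, so the last frame sits on the
# asymptote at double precision and the ideal crossing map is exact.
acceptance_video_spec <- function(seed, noise_sd = 0) {
  set.seed(seed)
  video_synth_spec(
    height = 64L, width = 64L, duration = 10, fps = 60,
    R0 = 40, R_inf = 240,
    k0 = stats::runif(1, 2.5, 4),
    lambda = stats::runif(1, 96, 256),
    center = c(stats::runif(1, 24, 40), stats::runif(1, 24, 40)),
    noise_sd = noise_sd, seed = seed
  )
}

# The criterion's own grid rule: smallest frame time strictly above the
# level-percentile of the crossing map (strict, because a pixel is mixed
# only strictly after its crossing time).
snap_t90_to_grid <- function(crossing, valid, fps, level = 90) {
  tv <- sort(crossing[valid])
  q <- tv[ceiling(level / 100 * length(tv))]
  (floor(q * fps) + 1) / fps
}
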