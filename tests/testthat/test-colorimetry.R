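mini_stack <- function(values_by_frame, fps = 60) {
  # build an H x W x T stack from a list of H x W matrices
  frames <- array(unlist(values_by_frame),
                  dim = c(dim(values_by_frame[[1L]]), length(values_by_frame)))
  frame_stack(frames, fps = fps)
}

test_that("to_grayscale applies weighted luma with half-up rounding", {
  mk_rgb <- function(r, g, b) {
    a <- array(0, dim = c(2, 2, 3, 2))
    a[, , 1, ] <- r; a[, , 2, ] <- g; a[, , 3, ] <- b
    a
  }
  # achromatic input is weight-independent
  gs <- to_grayscale(mk_rgb(200, 200, 200), fps = 60)
  expect_true(all(gs$frames == 200))
  gs2 <- to_grayscale(mk_rgb(200, 200, 200), weights = c(0.5, 0.25, 0.25), fps = 60)
  expect_true(all(gs2$frames == 200))
  # pure blue under ITU-R 601: round(0.114 * 255) = 29
  blue <- to_grayscale(mk_rgb(0, 0, 255), fps = 60)
  expect_true(all(blue$frames == 29))
  # already-grayscale stack passes through unchanged
  st <- mini_stack(list(matrix(10, 2, 2), matrix(20, 2, 2)))
  expect_identical(to_grayscale(st), st)
  # wrong channel count and bad weights are rejected
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2, 2)), fps = 60),
               class = "dissolvr_bad_channels")
  expect_error(to_grayscale(mk_rgb(0, 0, 0), weights = c(1, 1, 1), fps = 60),
               class = "dissolvr_bad_weights")
})

test_that("crop_roi subsets rectangles and records masks", {
  set.seed(11)
  st <- frame_stack(array(sample(0:255, 100 * 100 * 3, TRUE),
                          dim = c(100, 100, 3)), fps = 60)
  # full-frame rectangle is the identity
  full <- crop_roi(st, roi_rect(0, 0, 100, 100))
  expect_identical(full$frames, st$frames)
  # 10x10 rectangle
  sub <- crop_roi(st, roi_rect(5, 20, 10, 10))
  expect_identical(dim(sub$frames), c(10L, 10L, 3L))
  expect_identical(sub$frames[1, 1, 1], st$frames[6, 21, 1])
  # out-of-bounds rejected
  expect_error(crop_roi(st, roi_rect(95, 0, 10, 10)),
               class = "dissolvr_roi_bounds")
  # circular mask bounds n_valid downstream
  rr <- row(matrix(0, 100, 100)); cc <- col(matrix(0, 100, 100))
  disc <- (rr - 50)^2 + (cc - 50)^2 <= 30^2
  ramp <- mini_stack(list(matrix(0, 100, 100), matrix(255, 100, 100)))
  masked <- crop_roi(ramp, disc)
  tmap <- threshold_map(masked)
  expect_lte(sum(tmap$valid), sum(disc))
  expect_equal(sum(tmap$valid), sum(disc))  # every disc pixel is dynamic here
})

test_that("threshold_map interpolates between first and last frame", {
  st <- mini_stack(list(matrix(40, 4, 4), matrix(140, 4, 4), matrix(240, 4, 4)))
  tm <- threshold_map(st)
  expect_true(all(tm$beta == 140))
  expect_true(all(tm$valid))
  # X = 0 degenerates to the initial frame
  tm0 <- threshold_map(st, colorimetry_config(mixing_coefficient = 0))
  expect_true(all(tm0$beta == 40))
  # static pixel flagged invalid; beta stays within [R0, Rinf]
  fr <- array(100, dim = c(2, 2, 3))
  fr[1, 1, ] <- c(40, 150, 240)
  tms <- threshold_map(frame_stack(fr, fps = 60))
  expect_identical(tms$valid, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_true(all(tms$beta >= pmin(tms$r0, tms$rinf) - 1e-12 &
                    tms$beta <= pmax(tms$r0, tms$rinf) + 1e-12))
  # all-static stack is a no-dynamics error
  expect_error(threshold_map(mini_stack(list(matrix(100, 2, 2),
                                             matrix(104, 2, 2)))),
               class = "dissolvr_no_dynamics")
  # Rinf as mean of trailing frames
  tmn <- threshold_map(st, colorimetry_config(reference_last_n = 2))
  expect_true(all(tmn$rinf == 190))
})

test_that("classify_mixed uses a strict per-frame rule and zeroes invalid pixels", {
  fr <- array(0, dim = c(1, 3, 3))
  fr[1, 1, ] <- c(40, 141, 240)   # exceeds beta = 140 at frame 2
  fr[1, 2, ] <- c(40, 140, 240)   # exactly at beta: unmixed under strict rule
  fr[1, 3, ] <- c(100, 200, 100)  # static endpoints -> invalid
  st <- frame_stack(fr, fps = 60)
  tm <- threshold_map(st)
  bin <- classify_mixed(st, tm)
  expect_identical(bin[1, 1, ], c(FALSE, TRUE, TRUE))
  expect_identical(bin[1, 2, ], c(FALSE, FALSE, TRUE))
  expect_identical(bin[1, 3, ], c(FALSE, FALSE, FALSE))
  # non-strict variant flips the tie
  cfg <- colorimetry_config(strict = FALSE)
  bin2 <- classify_mixed(st, threshold_map(st, cfg))
  expect_identical(bin2[1, 2, ], c(FALSE, TRUE, TRUE))
  # no latching: a flickering pixel is re-evaluated each frame
  st2 <- frame_stack(array(c(0, 0, 200, 255, 0, 0, 255, 255),
                           dim = c(2, 1, 4)), fps = 60)
  bin3 <- classify_mixed(st2, threshold_map(st2))
  expect_identical(bin3[1, 1, ], c(FALSE, TRUE, FALSE, TRUE))
})

test_that("mixing_curve counts mixed valid pixels per frame", {
  # 100 pixels, 10 static, threshold 127.5; 81 of 90 valid pixels mixed at
  # the middle frame -> M = 90
  fr <- array(0, dim = c(10, 10, 3))
  fr[, , 3] <- 255
  fr[, , 2] <- 0
  idx <- cbind((seq_len(81) - 1) %% 10 + 1, (seq_len(81) - 1) %/% 10 + 1)
  fr[cbind(idx, rep(2, 81))] <- 200
  static <- cbind(1:10, rep(10, 10))  # column 10: disjoint from the 81 mixed
  for (k in 1:3) fr[cbind(static, rep(k, 10))] <- 50
  st <- frame_stack(fr, fps = 60)
  tm <- threshold_map(st)
  expect_equal(sum(tm$valid), 90)
  cur <- mixing_curve(classify_mixed(st, tm), tm, st)
  expect_equal(cur$M, c(0, 90, 100))
  expect_equal(cur$n_valid, 90)
  # degenerate single valid pixel
  st1 <- frame_stack(array(c(0, 100, 255, 100), dim = c(2, 1, 2)), fps = 60)
  tm1 <- threshold_map(st1)
  cur1 <- mixing_curve(classify_mixed(st1, tm1), tm1, st1)
  expect_equal(cur1$n_valid, 1)
  expect_equal(cur1$M, c(0, 100))
})

test_that("discoloration_time reports the first >= level frame or censors", {
  mk_curve <- function(M, fps = 60) {
    structure(list(times = (seq_along(M) - 1) / fps, M = M, n_valid = 100L,
                   fps = fps, t0_offset = 0), class = "mixing_curve")
  }
  M <- c(rep(0, 120), rep(95, 80))  # first >= 90 at 0-based frame 120
  res <- discoloration_time(mk_curve(M))
  expect_false(res$censored)
  expect_equal(res$t90, 2.0)
  expect_equal(res$frame_index, 120L)
  # all earlier frames below the level
  expect_true(all(res$curve$M[seq_len(res$frame_index)] < res$level))
  # never reaching the level censors at the video duration
  res2 <- discoloration_time(mk_curve(rep(85, 600)))
  expect_true(res2$censored)
  expect_equal(res2$t90, 10)
})

test_that("first_mixed_map takes the first crossing and ignores flicker", {
  fr <- array(0, dim = c(2, 2, 5))
  fr[1, 1, ] <- c(0, 0, 255, 0, 255)    # first mixed at frame 2 (0-based)
  fr[1, 2, ] <- c(255, 255, 255, 255, 255)
  fr[2, 1, ] <- c(0, 0, 0, 0, 0)
  fr[2, 2, ] <- c(0, 0, 0, 0, 255)
  # build thresholds from explicit first/last frames of a surrogate stack
  st <- frame_stack(fr, fps = 60)
  tm <- threshold_map(st)                       # (1,2) and (2,1) static
  fm <- first_mixed_map(classify_mixed(st, tm), st)
  expect_equal(fm[1, 1], 2 / 60)
  expect_true(is.na(fm[1, 2]))                  # invalid -> sentinel
  expect_true(is.na(fm[2, 1]))
  expect_equal(fm[2, 2], 4 / 60)
  # a pixel mixed from frame 0 maps to time 0
  bin <- array(TRUE, dim = c(1, 1, 3))
  fm0 <- first_mixed_map(bin, fps = 60)
  expect_equal(fm0[1, 1], 0)
})

test_that("pipeline M(t) equals the brute-force evaluation exactly", {
  for (seed in 1:3) {
    frames <- random_gray_stack(seed)
    st <- frame_stack(frames, fps = 60)
    tm <- threshold_map(st)
    cur <- mixing_curve(classify_mixed(st, tm), tm, st)
    oracle <- oracle_mixing_curve(frames)
    expect_equal(cur$M, oracle$M, tolerance = 0)
    expect_identical(cur$n_valid, oracle$n_valid)
    expect_equal(tm$beta, oracle$beta, tolerance = 0)
    expect_identical(tm$valid, oracle$valid)
  }
})

test_that("M(t) is non-decreasing for monotone inputs and t90 is X-monotone", {
  for (seed in 4:8) {
    frames <- monotone_gray_stack(seed)
    st <- frame_stack(frames, fps = 60)
    t90 <- vapply(c(0.25, 0.5, 0.75), function(x) {
      cfg <- colorimetry_config(mixing_coefficient = x)
      tm <- threshold_map(st, cfg)
      cur <- mixing_curve(classify_mixed(st, tm), tm, st)
      if (x == 0.5) expect_true(all(diff(cur$M) >= 0))
      discoloration_time(cur, cfg)$t90
    }, numeric(1L))
    expect_true(t90[1] <= t90[2] && t90[2] <= t90[3])
  }
})

test_that("classification and t90 are invariant to a constant gray shift", {
  frames <- random_gray_stack(42) * 0.5  # leave headroom for the shift
  st <- frame_stack(frames, fps = 60)
  st2 <- frame_stack(frames + 60, fps = 60)
  tm <- threshold_map(st); tm2 <- threshold_map(st2)
  expect_identical(tm$valid, tm2$valid)
  b <- classify_mixed(st, tm); b2 <- classify_mixed(st2, tm2)
  expect_identical(b, b2)
  c1 <- mixing_curve(b, tm, st); c2 <- mixing_curve(b2, tm2, st2)
  expect_identical(c1$M, c2$M)
  expect_identical(discoloration_time(c1)$t90, discoloration_time(c2)$t90)
})

test_that("noiseless synthetic video recovery is exact on the frame grid", {
  sv <- synth_video(video_synth_spec(height = 32L, width = 32L, duration = 6))
  an <- analyze_video(sv$stack)
  # pipeline t90 equals the ground-truth grid value exactly
  expect_identical(an$result$t90, sv$truth$t90_grid)
  # each pixel's first-mixed time equals its windowed closed-form crossing
  # snapped up to the frame grid
  fps <- sv$stack$fps
  expected <- (floor(sv$truth$crossing_windowed * fps) + 1) / fps
  got <- unclass(an$first_mixed)
  expect_true(all(sv$truth$valid))
  expect_equal(got, expected, tolerance = 0, ignore_attr = TRUE)
  # default generator world: windowed and ideal maps agree to < 1 ms/frame tol
  expect_lt(max(abs(sv$truth$crossing - sv$truth$crossing_windowed)), 1e-3)
})
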