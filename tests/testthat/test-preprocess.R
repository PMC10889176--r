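test_that("resampling reproduces constants and linear ramps exactly", {
  t <- seq(0, 2, by = 1 / 120)
  const <- resample_to_uniform(toy_recording(t, rep(5, length(t))))
  expect_true(all(const$values == 5))
  expect_equal(const$fs, 60)
  # 2 s at 120 Hz -> 121 points on the 60 Hz grid (t in [0, 2])
  expect_equal(length(const$values), 121)
  ramp <- resample_to_uniform(toy_recording(t, 4 + 0.3 * t))
  expect_lt(max(abs(ramp$values - (4 + 0.3 * trace_times(ramp)))), 1e-9)
  # low-confidence raw samples invalidate the grid points they bracket
  conf <- rep(0.98, length(t)); conf[t >= 0.5 & t <= 0.6] <- 0.1
  tr <- resample_to_uniform(toy_recording(t, rep(5, length(t)), conf))
  tt <- trace_times(tr)
  expect_true(all(!tr$valid[tt > 0.5 & tt < 0.6]))
  expect_true(all(tr$valid[tt < 0.4 | tt > 0.7]))
  expect_error(resample_to_uniform(toy_recording(c(0, 0.005), c(1, 1))),
               "too short")
})

test_that("blink detection finds inserted blinks and nothing else", {
  t <- seq(0, 5, by = 1 / 120)
  clean <- resample_to_uniform(toy_recording(t, rep(4, length(t))))
  expect_equal(nrow(detect_blinks(clean)), 0)
  # one blink: diameter collapses for 150 ms with low confidence
  set.seed(12)
  d <- 4 + rnorm(length(t), 0, 0.01)
  conf <- rep(0.98, length(t))
  blink <- t >= 2.0 & t <= 2.15
  d[blink] <- 0; conf[blink] <- 0.02
  tr <- resample_to_uniform(toy_recording(t, d, conf))
  iv <- detect_blinks(tr)
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv$start - 2.0), 1 / 60 + 1e-9)
  expect_lt(abs(iv$end - 2.15), 1 / 60 + 1e-9)
  # two blinks separated by a second give two disjoint intervals
  d2 <- 4 + rnorm(length(t), 0, 0.01); conf2 <- rep(0.98, length(t))
  b1 <- t >= 1.0 & t <= 1.12; b2 <- t >= 3.0 & t <= 3.12
  d2[b1 | b2] <- 0; conf2[b1 | b2] <- 0.02
  iv2 <- detect_blinks(resample_to_uniform(toy_recording(t, d2, conf2)))
  expect_equal(nrow(iv2), 2)
  expect_lt(iv2$end[1], iv2$start[2])
})

test_that("blink margins invalidate 35 ms before and 100 ms after", {
  tr <- uniform_trace(0, 60, rep(4, 241))
  out <- apply_blink_margins(tr, data.frame(start = 2.000, end = 2.150))
  tt <- trace_times(out)
  expect_true(all(!out$valid[tt >= 1.965 - 1e-9 & tt <= 2.250 + 1e-9]))
  expect_true(all(out$valid[tt < 1.965 - 1e-9 | tt > 2.250 + 1e-9]))
  # empty interval list leaves the trace unchanged
  expect_identical(apply_blink_margins(tr, data.frame(start = numeric(0),
                                                      end = numeric(0))),
                   tr)
  # overlapping expansions merge into one contiguous invalid run
  out2 <- apply_blink_margins(tr, data.frame(start = c(1.0, 1.2),
                                             end = c(1.1, 1.3)))
  r <- rle(out2$valid)
  expect_equal(sum(!r$values), 1)   # exactly one contiguous invalid run
})

test_that("outlier rule removes deviants and short valid islands", {
  set.seed(5)
  v <- rnorm(120, 4, 0.01)
  tr <- uniform_trace(0, 60, v)
  m <- mean(v); s <- sd(v)
  tr$values[50] <- m + 5 * s
  out <- remove_outliers(tr)
  expect_false(out$valid[50])
  expect_true(all(out$valid[-50]))
  # all samples within 1 SD -> unchanged
  tr2 <- uniform_trace(0, 60, 4 + 0.5 * sin(seq(0, 2 * pi, length.out = 60)))
  expect_identical(remove_outliers(tr2)$valid, tr2$valid)
  # a 2-sample valid island (33 ms at 60 Hz < 40 ms) is pruned,
  # a 3-sample island (50 ms) survives
  valid <- rep(TRUE, 60)
  valid[10:20] <- FALSE; valid[23:40] <- FALSE   # island 21:22
  tr3 <- uniform_trace(0, 60, rep(4, 60), valid)
  out3 <- remove_outliers(tr3)
  expect_true(all(!out3$valid[21:22]))
  valid2 <- rep(TRUE, 60)
  valid2[10:20] <- FALSE; valid2[24:40] <- FALSE  # island 21:23
  tr4 <- uniform_trace(0, 60, rep(4, 60), valid2)
  expect_true(all(remove_outliers(tr4)$valid[21:23]))
})

test_that("gap interpolation bridges short gaps only, never at edges", {
  t <- (0:120) / 60
  ramp <- 4 + 0.5 * t
  valid <- rep(TRUE, 121)
  valid[40:45] <- FALSE                 # 6 samples = 100 ms
  tr <- uniform_trace(0, 60, ifelse(valid, ramp, 0), valid)
  out <- interpolate_gaps(tr, max_gap = 0.3)
  expect_true(all(out$valid[40:45]))
  expect_true(all(out$interpolated[40:45]))
  expect_lt(max(abs(out$values[40:45] - ramp[40:45])), 1e-9)
  expect_equal(out$removed_fraction, tr$removed_fraction)  # loss still counted
  # 500 ms gap stays invalid
  valid2 <- rep(TRUE, 121); valid2[40:69] <- FALSE
  tr2 <- uniform_trace(0, 60, ramp, valid2)
  expect_true(all(!interpolate_gaps(tr2, 0.3)$valid[40:69]))
  # edge gaps are never extrapolated
  valid3 <- rep(TRUE, 121); valid3[1:5] <- FALSE; valid3[118:121] <- FALSE
  out3 <- interpolate_gaps(uniform_trace(0, 60, ramp, valid3), 0.3)
  expect_true(all(!out3$valid[c(1:5, 118:121)]))
})

test_that("moving-average smoothing behaves like a 3-point mean at 60 Hz", {
  # constant unchanged
  tr <- uniform_trace(0, 60, rep(4, 50))
  expect_equal(smooth_moving_average(tr)$values, rep(4, 50))
  # single spike of height h flanked by zeros -> h/3
  v <- rep(0, 31); v[16] <- 0.9
  out <- smooth_moving_average(uniform_trace(0, 60, v))
  expect_equal(out$values[16], 0.3)
  expect_equal(out$values[15], 0.3)
  # linear ramp interior unchanged
  ramp <- seq(0, 1, length.out = 61)
  sm <- smooth_moving_average(uniform_trace(0, 60, ramp))
  expect_lt(max(abs(sm$values[2:60] - ramp[2:60])), 1e-12)
  # window shorter than one sample interval is rejected
  expect_error(smooth_moving_average(tr, window = 0.001), "window")
})

test_that("exclusion keeps exactly 50% removed and rejects more", {
  n <- 300
  half <- uniform_trace(0, 60, rnorm(n), valid = rep(c(TRUE, FALSE), n / 2))
  expect_equal(half$removed_fraction, 0.5)
  expect_true(exclusion_check(half))
  worse <- uniform_trace(0, 60, rnorm(n),
                         valid = c(rep(FALSE, 153), rep(TRUE, 147)))
  expect_equal(worse$removed_fraction, 0.51)
  expect_false(exclusion_check(worse))
  expect_true(exclusion_check(uniform_trace(0, 60, rnorm(n))))
})

test_that("each operator matches its brute-force reference exactly", {
  # toy recordings (<= 30 raw samples) through resampling
  set.seed(8)
  t_raw <- cumsum(runif(25, 0.005, 0.012))
  rec <- toy_recording(t_raw, 4 + cumsum(rnorm(25, 0, 0.02)),
                       conf = sample(c(0.98, 0.4), 25, TRUE, c(0.85, 0.15)))
  expect_trace_equal(resample_to_uniform(rec), ref_resample(rec))

  tr <- toy_trace_with_blink()
  expect_equal(detect_blinks(tr), ref_detect_blinks(tr))

  iv <- detect_blinks(tr)
  expect_trace_equal(apply_blink_margins(tr, iv),
                     ref_apply_margins(tr, iv))

  set.seed(21)
  tro <- uniform_trace(0, 60, c(rnorm(27, 4, 0.01), 4.5, 4, 4))
  expect_trace_equal(remove_outliers(tro), ref_remove_outliers(tro))

  trg <- uniform_trace(0, 60, 4 + (0:29) * 0.01,
                       valid = c(rep(TRUE, 10), rep(FALSE, 4),
                                 rep(TRUE, 16)))
  expect_trace_equal(interpolate_gaps(trg, 0.3), ref_interpolate(trg, 0.3))

  set.seed(22)
  trs <- uniform_trace(0, 60, rnorm(30, 4, 0.1),
                       valid = sample(c(TRUE, FALSE), 30, TRUE,
                                      c(0.8, 0.2)))
  expect_trace_equal(smooth_moving_average(trs), ref_smooth(trs))
})

test_that("outlier removal is idempotent on surviving in-range samples", {
  set.seed(33)
  for (i in 1:10) {
    tr <- uniform_trace(0, 60, rnorm(200, 4, 0.05),
                        valid = runif(200) > 0.1)
    once <- remove_outliers(tr)
    v <- once$values[once$valid]
    if (all(abs(v - mean(v)) <= 2.5 * sd(v))) {
      expect_identical(remove_outliers(once)$valid, once$valid)
    }
  }
})

test_that("the full chain passes clean well-behaved signals through", {
  # blink-free, noise-free input within the outlier envelope
  t <- seq(0, 4, by = 1 / 120)
  d <- 4 + 0.05 * sin(2 * pi * t / 4)
  rec <- toy_recording(t, d)
  out <- preprocess_recording(rec)
  tt <- trace_times(out)
  interior <- tt > 0.2 & tt < 3.8
  truth <- 4 + 0.05 * sin(2 * pi * tt / 4)
  expect_true(all(out$valid))
  # 3-point moving average of a smooth sinusoid: tiny attenuation only
  expect_lt(max(abs(out$values[interior] - truth[interior])), 2e-5)
})

test_that("alternative outlier reading removes only short deviant runs", {
  set.seed(44)
  v <- rnorm(120, 4, 0.01)
  v[60] <- 5         # 1-sample deviant run (17 ms): removed
  v[80:90] <- 5      # 11-sample deviant run (183 ms): kept under this mode
  tr <- uniform_trace(0, 60, v)
  out <- remove_outliers(tr, mode = "short_deviant_runs_only")
  expect_false(out$valid[60])
  expect_true(all(out$valid[80:90]))
})
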