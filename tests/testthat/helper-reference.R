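# Independent brute-force reference implementations of every cleaning
# operator, written as plain loops straight from the documented
# definitions. They share no code with the package internals and serve
# as the oracle for exact-equivalence tests on small toy traces.

ref_resample <- function(rec, fs = 60, conf_floor = 0.6) {
  s <- rec$samples
  t0 <- s$t[1]
  n <- floor((s$t[nrow(s)] - t0) * fs + 1e-9) + 1
  vals <- numeric(n); conf <- numeric(n)
  for (k in seq_len(n)) {
    tk <- t0 + (k - 1) / fs
    j <- max(which(s$t <= tk + 1e-12))
    if (j == nrow(s)) {
      vals[k] <- s$diameter[j]; conf[k] <- s$confidence[j]
    } else {
      w <- (tk - s$t[j]) / (s$t[j + 1] - s$t[j])
      vals[k] <- (1 - w) * s$diameter[j] + w * s$diameter[j + 1]
      conf[k] <- (1 - w) * s$confidence[j] + w * s$confidence[j + 1]
    }
  }
  uniform_trace(t0, fs, vals, valid = conf >= conf_floor)
}

# per-sample speed: larger absolute first difference to either neighbour,
# undefined (ignored) across invalid samples
ref_speeds <- function(trace) {
  n <- length(trace$values)
  sp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- c()
    if (i > 1 && trace$valid[i] && trace$valid[i - 1]) {
      cand <- c(cand, abs(trace$values[i] - trace$values[i - 1]) * trace$fs)
    }
    if (i < n && trace$valid[i] && trace$valid[i + 1]) {
      cand <- c(cand, abs(trace$values[i + 1] - trace$values[i]) * trace$fs)
    }
    if (length(cand)) sp[i] <- max(cand)
  }
  sp
}

ref_detect_blinks <- function(trace, k_mad = 3, loss_fraction = 0.5) {
  sp <- ref_speeds(trace)
  pool <- sp[trace$valid & !is.na(sp)]
  thr <- median(pool) + k_mad * mad(pool)
  flagged <- logical(length(trace$values))
  for (i in seq_along(flagged)) {
    flagged[i] <- !trace$valid[i] || (!is.na(sp[i]) && sp[i] > thr)
  }
  med <- median(trace$values[trace$valid])
  t <- trace$t0 + (seq_along(flagged) - 1) / trace$fs
  out <- data.frame(start = numeric(0), end = numeric(0))
  i <- 1
  while (i <= length(flagged)) {
    if (flagged[i]) {
      j <- i
      while (j < length(flagged) && flagged[j + 1]) j <- j + 1
      lost <- FALSE
      for (q in i:j) {
        if (!trace$valid[q] || trace$values[q] < loss_fraction * med) {
          lost <- TRUE
        }
      }
      if (lost) out <- rbind(out, data.frame(start = t[i], end = t[j]))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

ref_apply_margins <- function(trace, intervals, pre = 0.035, post = 0.100) {
  t <- trace$t0 + (seq_along(trace$values) - 1) / trace$fs
  for (r in seq_len(nrow(intervals))) {
    for (i in seq_along(t)) {
      if (t[i] >= intervals$start[r] - pre - 1e-9 &&
          t[i] <= intervals$end[r] + post + 1e-9) {
        trace$valid[i] <- FALSE
      }
    }
  }
  trace$removed_fraction <- 1 - mean(trace$valid & !trace$interpolated)
  trace
}

ref_remove_outliers <- function(trace, z = 2.5, min_len = 0.040) {
  v <- trace$values[trace$valid]
  m <- mean(v); s <- sd(v)
  for (i in seq_along(trace$values)) {
    if (trace$valid[i] && s > 0 && abs(trace$values[i] - m) > z * s) {
      trace$valid[i] <- FALSE
    }
  }
  # prune valid islands strictly shorter than min_len
  n <- length(trace$valid)
  i <- 1
  while (i <= n) {
    if (trace$valid[i]) {
      j <- i
      while (j < n && trace$valid[j + 1]) j <- j + 1
      if ((j - i + 1) / trace$fs < min_len - 1e-9) {
        for (q in i:j) trace$valid[q] <- FALSE
      }
      i <- j + 1
    } else i <- i + 1
  }
  trace$removed_fraction <- 1 - mean(trace$valid & !trace$interpolated)
  trace
}

ref_interpolate <- function(trace, max_gap = 0.3) {
  n <- length(trace$values)
  i <- 1
  while (i <= n) {
    if (!trace$valid[i]) {
      j <- i
      while (j < n && !trace$valid[j + 1]) j <- j + 1
      len <- (j - i + 1) / trace$fs
      if (len <= max_gap + 1e-9 && i > 1 && j < n &&
          trace$valid[i - 1] && trace$valid[j + 1]) {
        for (q in i:j) {
          w <- (q - (i - 1)) / ((j + 1) - (i - 1))
          trace$values[q] <- (1 - w) * trace$values[i - 1] +
            w * trace$values[j + 1]
          trace$valid[q] <- TRUE
          trace$interpolated[q] <- TRUE
        }
      }
      i <- j + 1
    } else i <- i + 1
  }
  trace$removed_fraction <- 1 - mean(trace$valid & !trace$interpolated)
  trace
}

ref_smooth <- function(trace, window = 0.050) {
  n <- length(trace$values)
  k <- floor(window / 2 * trace$fs + 1e-9)
  out <- trace$values
  for (i in seq_len(n)) {
    if (!trace$valid[i]) next
    acc <- 0; cnt <- 0
    for (j in max(1, i - k):min(n, i + k)) {
      if (trace$valid[j]) { acc <- acc + trace$values[j]; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt
  }
  trace$values <- out
  trace
}

ref_baseline_epoch <- function(values, rel_time, valid) {
  sel <- valid & rel_time >= -1 - 1e-9 & rel_time < -1e-9
  values - mean(values[sel])
}

# -- shared toy builders -------------------------------------------------

toy_recording <- function(t, d, conf = rep(0.98, length(t))) {
  pupil_recording(data.frame(t = t, diameter = d, confidence = conf))
}

# small noisy trace with an embedded blink, for exact-equivalence tests
toy_trace_with_blink <- function(seed = 1, n = 30, fs = 60) {
  set.seed(seed)
  v <- 4 + cumsum(rnorm(n, 0, 0.01))
  valid <- rep(TRUE, n)
  v[14:16] <- 0            # blink: collapse to zero
  valid[14:16] <- FALSE    # confidence already flagged it
  uniform_trace(0, fs, v, valid)
}

expect_trace_equal <- function(a, b) {
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_identical(a$valid, b$valid)
  expect_identical(a$interpolated, b$interpolated)
  expect_equal(a$removed_fraction, b$removed_fraction, tolerance = 1e-12)
}
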