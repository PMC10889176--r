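#' Preprocessing parameters for the pupil cleaning chain
#'
#' Bundles every tunable of the cleaning chain with its default. The
#' chain applies, in a fixed order: resampling to a uniform grid, blink
#' detection by median-absolute-deviation thresholding of dilation speed,
#' pre/post blink margins, standard-deviation outlier removal with
#' short-island pruning, gap interpolation, and moving-average smoothing.
#' Epoch-level exclusion (more than 50% of points removed) is applied at
#' epoching time, the unit over which curves are averaged.
#'
#' @param fs Target uniform sampling rate, Hz (default 60).
#' @param conf_floor Tracker-confidence floor below which resampled points
#'   are marked invalid (default 0.6).
#' @param k_mad Multiplier on the MAD of dilation speed in the blink
#'   threshold `median + k_mad * MAD` (default 3). The MAD uses the
#'   normal-consistent scaling (as [stats::mad()]).
#' @param pre_margin,post_margin Seconds discarded before/after each
#'   detected blink (defaults 0.035 and 0.100).
#' @param z Outlier threshold in standard deviations from the mean of the
#'   valid samples (default 2.5).
#' @param min_len Minimum duration (s) a run must have to survive the
#'   short-segment rule (default 0.040).
#' @param outlier_mode `"deviants_and_short_islands"` (default): remove
#'   points beyond `z` SD, then invalidate any surviving valid island
#'   shorter than `min_len`; `"short_deviant_runs_only"`: only remove
#'   deviant runs that are themselves shorter than `min_len` (the
#'   alternative reading of the 2.5 SD / 40 ms rule).
#' @param outlier_scope `"trace"` (default): the mean/SD are computed over
#'   the whole trace; `"segment"`: per trial segment when events are
#'   supplied to [preprocess_recording()].
#' @param max_gap Longest invalid run (s) bridged by linear interpolation
#'   (default 0.3); longer gaps stay invalid. Set to 0 to disable
#'   interpolation (cleaned points are then simply dropped from averages).
#' @param smooth_window Moving-average window length, s (default 0.050).
#' @param max_removed Exclusion threshold: an epoch (or trace, via
#'   [exclusion_check()]) with strictly more than this fraction of points
#'   removed is excluded (default 0.5).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(fs = 60, conf_floor = 0.6, k_mad = 3,
                              pre_margin = 0.035, post_margin = 0.100,
                              z = 2.5, min_len = 0.040,
                              outlier_mode = c("deviants_and_short_islands",
                                               "short_deviant_runs_only"),
                              outlier_scope = c("trace", "segment"),
                              max_gap = 0.3, smooth_window = 0.050,
                              max_removed = 0.5) {
  outlier_mode <- match.arg(outlier_mode)
  outlier_scope <- match.arg(outlier_scope)
  stopifnot(fs > 0, conf_floor >= 0, conf_floor <= 1, k_mad >= 0,
            pre_margin >= 0, post_margin >= 0, z > 0, min_len >= 0,
            max_gap >= 0, smooth_window >= 0,
            max_removed >= 0, max_removed <= 1)
  structure(list(fs = fs, conf_floor = conf_floor, k_mad = k_mad,
                 pre_margin = pre_margin, post_margin = post_margin,
                 z = z, min_len = min_len, outlier_mode = outlier_mode,
                 outlier_scope = outlier_scope, max_gap = max_gap,
                 smooth_window = smooth_window, max_removed = max_removed),
            class = "preprocess_params")
}

#' Construct a uniformly sampled trace
#'
#' The container all preprocessing operators transform: a diameter series
#' on the grid `t0 + (k-1)/fs`, a `valid` mask (points currently usable),
#' and an `interpolated` mask (points whose value was reconstructed by
#' gap interpolation rather than measured). `removed_fraction` is the
#' fraction of points that are not measured-and-valid, i.e. it records
#' pre-interpolation data loss and is not reduced by interpolation.
#'
#' @param t0 Time of the first sample, s.
#' @param fs Sampling rate, Hz.
#' @param values Numeric diameter series.
#' @param valid Logical mask, same length as `values`.
#' @param interpolated Logical mask of interpolated points.
#' @return Object of class `uniform_trace`.
#' @export
uniform_trace <- function(t0, fs, values, valid = rep(TRUE, length(values)),
                          interpolated = rep(FALSE, length(values))) {
  stopifnot(fs > 0, length(valid) == length(values),
            length(interpolated) == length(values))
  x <- structure(list(t0 = t0, fs = fs, values = as.numeric(values),
                      valid = as.logical(valid),
                      interpolated = as.logical(interpolated)),
                 class = "uniform_trace")
  x$removed_fraction <- removed_fraction(x)
  x
}

#' @rdname uniform_trace
#' @param trace A `uniform_trace`.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1L) / trace$fs
}

#' @rdname uniform_trace
#' @export
removed_fraction <- function(trace) {
  1 - mean(trace$valid & !trace$interpolated)
}

#' @export
print.uniform_trace <- function(x, ...) {
  cat(sprintf(
    "<uniform_trace> %d points @ %g Hz from t=%.3f s, %.1f%% removed\n",
    length(x$values), x$fs, x$t0, 100 * x$removed_fraction))
  invisible(x)
}

#' Resample a raw recording onto a uniform grid
#'
#' Linearly interpolates the raw diameter samples onto the grid
#' `t0 + (k-1)/fs` spanning the recording, where `t0` is the first raw
#' timestamp. Grid points whose (interpolated) tracker confidence falls
#' below `conf_floor` are marked invalid.
#'
#' @param rec A [pupil_recording()].
#' @param fs Target rate in Hz (default 60).
#' @param conf_floor Confidence floor for validity (default 0.6).
#' @return A [uniform_trace()].
#' @export
resample_to_uniform <- function(rec, fs = 60, conf_floor = 0.6) {
  stopifnot(inherits(rec, "pupil_recording"))
  s <- rec$samples
  span <- s$t[nrow(s)] - s$t[1]
  if (nrow(s) < 2L || span <= 1 / fs) {
    stop("recording too short to resample: need >= 2 samples spanning ",
         "more than one target sample interval")
  }
  n <- floor(span * fs + 1e-9) + 1L
  tout <- s$t[1] + (seq_len(n) - 1L) / fs
  vals <- stats::approx(s$t, s$diameter, xout = tout)$y
  conf <- stats::approx(s$t, s$confidence, xout = tout)$y
  uniform_trace(t0 = s$t[1], fs = fs, values = vals,
                valid = conf >= conf_floor)
}

# Per-sample dilation speed (au/s): a sample carries the larger of the
# absolute first differences to its two neighbours, so both endpoints of
# a jump are flagged. Differences across invalid samples are undefined
# (NA) and excluded from the threshold statistics.
sample_speed <- function(trace) {
  v <- trace$values
  d <- abs(diff(v)) * trace$fs
  pair_ok <- trace$valid[-length(v)] & trace$valid[-1]
  d[!pair_ok] <- NA_real_
  fwd <- c(d, NA_real_)   # speed to the next sample
  bwd <- c(NA_real_, d)   # speed from the previous sample
  pmax(fwd, bwd, na.rm = TRUE)
}

#' Detect blinks by thresholding dilation speed
#'
#' Computes the absolute sample-to-sample dilation speed and flags samples
#' whose speed exceeds `median + k_mad * MAD` of the speed distribution
#' (MAD with normal-consistent scaling), or whose confidence already
#' marked them invalid. Maximal runs of flagged samples form candidate
#' intervals; a candidate is confirmed as a blink when it shows actual
#' signal loss — it touches confidence-invalid samples or the measured
#' diameter inside it collapses below half the trace's median. The
#' confirmation step keeps fast-but-physiological dilation (and isolated
#' noise spikes, which the outlier rule handles) from being treated as
#' eyelid closures.
#'
#' @param trace A [uniform_trace()].
#' @param k_mad MAD multiplier (default 3).
#' @param loss_fraction Fraction of the median valid diameter below which
#'   a sample counts as signal loss (default 0.5).
#' @return Data frame with columns `start`, `end` (seconds, sample times);
#'   zero rows when the trace is clean. An all-invalid trace yields an
#'   empty list with a warning.
#' @export
detect_blinks <- function(trace, k_mad = 3, loss_fraction = 0.5) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (sum(trace$valid) < 10L) {
    warning("fewer than 10 valid samples; blink detection skipped")
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  speed <- sample_speed(trace)
  sp <- speed[trace$valid & !is.na(speed)]
  thr <- stats::median(sp) + k_mad * stats::mad(sp)
  flagged <- !trace$valid | (!is.na(speed) & speed > thr)
  lost <- !trace$valid |
    trace$values < loss_fraction * stats::median(trace$values[trace$valid])
  runs_to_intervals(flagged, trace, confirm = lost)
}

runs_to_intervals <- function(flagged, trace, confirm = NULL) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!is.null(confirm)) {
    for (i in which(keep)) {
      if (!any(confirm[starts[i]:ends[i]])) keep[i] <- FALSE
    }
  }
  t <- trace_times(trace)
  data.frame(start = t[starts[keep]], end = t[ends[keep]])
}

#' Discard margins around detected blinks
#'
#' Clears the validity mask on `[start - pre_margin, end + post_margin]`
#' for every interval; expanded intervals that overlap merge into one
#' contiguous invalid run.
#'
#' @param trace A [uniform_trace()].
#' @param intervals Data frame with `start`/`end` columns (s), e.g. from
#'   [detect_blinks()].
#' @param pre_margin Seconds discarded before each interval (default 0.035).
#' @param post_margin Seconds discarded after each interval (default 0.100).
#' @return The trace with the mask updated.
#' @export
apply_blink_margins <- function(trace, intervals, pre_margin = 0.035,
                                post_margin = 0.100) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (nrow(intervals) == 0L) return(trace)
  t <- trace_times(trace)
  eps <- 1e-9
  for (i in seq_len(nrow(intervals))) {
    hit <- t >= intervals$start[i] - pre_margin - eps &
      t <= intervals$end[i] + post_margin + eps
    trace$valid[hit] <- FALSE
  }
  trace$removed_fraction <- removed_fraction(trace)
  trace
}

#' Remove statistical outliers and unreliable short segments
#'
#' Two rules derived from the 2.5 SD / 40 ms convention, with the reading
#' selected by `mode`:
#' \describe{
#'   \item{`deviants_and_short_islands` (default)}{valid samples deviating
#'     more than `z` SDs from the valid-sample mean are invalidated; then
#'     any surviving valid island (maximal valid run) strictly shorter
#'     than `min_len` is invalidated as an unreliable fragment.}
#'   \item{`short_deviant_runs_only`}{only maximal runs of deviant samples
#'     that are strictly shorter than `min_len` are invalidated.}
#' }
#'
#' @param trace A [uniform_trace()].
#' @param z SD multiplier (default 2.5).
#' @param min_len Duration threshold in seconds (default 0.040); a run of
#'   `k` samples has duration `k / fs`.
#' @param mode See above.
#' @return The trace with the mask updated.
#' @export
remove_outliers <- function(trace, z = 2.5, min_len = 0.040,
                            mode = c("deviants_and_short_islands",
                                     "short_deviant_runs_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "uniform_trace"))
  if (sum(trace$valid) < 10L) return(trace)
  v <- trace$values
  m <- mean(v[trace$valid])
  s <- stats::sd(v[trace$valid])
  deviant <- trace$valid & s > 0 & abs(v - m) > z * s
  min_samples <- min_len * trace$fs   # runs strictly shorter are pruned
  if (mode == "deviants_and_short_islands") {
    trace$valid[deviant] <- FALSE
    r <- rle(trace$valid)
    short <- r$values & r$lengths < min_samples - 1e-9
    if (any(short)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(short)) trace$valid[starts[i]:ends[i]] <- FALSE
    }
  } else {
    r <- rle(deviant)
    short <- r$values & r$lengths < min_samples - 1e-9
    if (any(short)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (i in which(short)) trace$valid[starts[i]:ends[i]] <- FALSE
    }
  }
  trace$removed_fraction <- removed_fraction(trace)
  trace
}

#' Bridge short gaps by linear interpolation
#'
#' Invalid runs no longer than `max_gap` that are flanked by valid
#' samples on both sides are filled linearly and marked
#' valid-but-interpolated; longer runs and runs touching the trace edges
#' are left invalid (no extrapolation). `removed_fraction` is unchanged:
#' it keeps recording the pre-interpolation loss.
#'
#' @param trace A [uniform_trace()].
#' @param max_gap Longest bridged gap in seconds (default 0.3); a gap of
#'   `k` samples has duration `k / fs`.
#' @return The trace with gaps bridged.
#' @export
interpolate_gaps <- function(trace, max_gap = 0.3) {
  stopifnot(inherits(trace, "uniform_trace"))
  n <- length(trace$values)
  r <- rle(trace$valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(!r$values)) {
    k <- r$lengths[i]
    if (k / trace$fs > max_gap + 1e-9) next
    lo <- starts[i] - 1L; hi <- ends[i] + 1L
    if (lo < 1L || hi > n) next                    # edge gap: never extrapolate
    if (!trace$valid[lo] || !trace$valid[hi]) next
    idx <- starts[i]:ends[i]
    w <- (idx - lo) / (hi - lo)
    trace$values[idx] <- (1 - w) * trace$values[lo] + w * trace$values[hi]
    trace$valid[idx] <- TRUE
    trace$interpolated[idx] <- TRUE
  }
  trace$removed_fraction <- removed_fraction(trace)
  trace
}

#' Moving-average smoothing over valid samples
#'
#' Centered moving average of half-width `window/2` seconds, computed over
#' the valid samples inside the window only; the effective window shrinks
#' at the trace edges and across invalid neighbours, so no data are
#' invented. Invalid samples are left untouched. Constant signals are
#' unchanged.
#'
#' @param trace A [uniform_trace()].
#' @param window Full window length in seconds (default 0.050; at 60 Hz
#'   this is a 3-point window).
#' @return The trace with smoothed values.
#' @export
smooth_moving_average <- function(trace, window = 0.050) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (window < 1 / trace$fs) {
    stop("smoothing window must be at least one sample interval")
  }
  k <- floor(window / 2 * trace$fs + 1e-9)   # half-width in samples
  if (k == 0L) return(trace)
  v <- ifelse(trace$valid, trace$values, 0)
  w <- as.numeric(trace$valid)
  kern <- rep(1, 2L * k + 1L)
  num <- stats::filter(v, kern, sides = 2)
  den <- stats::filter(w, kern, sides = 2)
  # filter() returns NA at the edges; recompute there with the shrunk window
  n <- length(v)
  for (i in c(seq_len(min(k, n)), seq.int(max(n - k + 1L, 1L), n))) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    num[i] <- sum(v[lo:hi]); den[i] <- sum(w[lo:hi])
  }
  sm <- ifelse(den > 0, as.numeric(num) / as.numeric(den), trace$values)
  trace$values <- ifelse(trace$valid, sm, trace$values)
  trace
}

#' Should a trace (or epoch) be kept?
#'
#' A unit of data is excluded when strictly more than `max_removed` of
#' its points were removed during cleaning; exactly 50% removed is kept.
#'
#' @param trace A [uniform_trace()] (its `removed_fraction` is used).
#' @param max_removed Exclusion threshold (default 0.5).
#' @return Logical: keep this trace?
#' @export
exclusion_check <- function(trace, max_removed = 0.5) {
  stopifnot(inherits(trace, "uniform_trace"))
  trace$removed_fraction <= max_removed
}

#' Run the full cleaning chain on a raw recording
#'
#' Applies, in order: [resample_to_uniform()], [detect_blinks()],
#' [apply_blink_margins()], [remove_outliers()], [interpolate_gaps()],
#' [smooth_moving_average()]. Epoch-level exclusion happens later, at
#' [epoch_trace()], the unit over which curves are averaged. When
#' `events` is supplied and `outlier_scope = "segment"`, outlier
#' statistics are computed per trial segment instead of over the whole
#' recording.
#'
#' @param rec A [pupil_recording()].
#' @param params A [preprocess_params()].
#' @param events Optional event log (see [read_events()]) for
#'   segment-scoped outlier removal.
#' @return A cleaned [uniform_trace()].
#' @export
preprocess_recording <- function(rec, params = preprocess_params(),
                                 events = NULL) {
  trace <- resample_to_uniform(rec, fs = params$fs,
                               conf_floor = params$conf_floor)
  blinks <- detect_blinks(trace, k_mad = params$k_mad)
  trace <- apply_blink_margins(trace, blinks,
                               pre_margin = params$pre_margin,
                               post_margin = params$post_margin)
  if (params$outlier_scope == "segment" && !is.null(events)) {
    t <- trace_times(trace)
    for (i in seq_len(nrow(events))) {
      idx <- which(t >= events$noise_on[i] & t <= events$noise_off[i])
      if (length(idx) < 10L) next
      seg <- uniform_trace(t[idx[1]], trace$fs, trace$values[idx],
                           trace$valid[idx], trace$interpolated[idx])
      seg <- remove_outliers(seg, z = params$z, min_len = params$min_len,
                             mode = params$outlier_mode)
      trace$valid[idx] <- seg$valid
    }
    trace$removed_fraction <- removed_fraction(trace)
  } else {
    trace <- remove_outliers(trace, z = params$z, min_len = params$min_len,
                             mode = params$outlier_mode)
  }
  if (params$max_gap > 0) {
    trace <- interpolate_gaps(trace, max_gap = params$max_gap)
  }
  if (params$smooth_window >= 1 / trace$fs) {
    trace <- smooth_moving_average(trace, window = params$smooth_window)
  }
  trace
}
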