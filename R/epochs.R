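#' Cut a cleaned trace into baseline-corrected sentence epochs
#'
#' For every trial in the event log, the trace is sampled onto a fixed
#' relative grid from `window[1]` (default 1 s before sentence onset) to
#' `window[2]` (default 4 s after onset, the average noise offset) at the
#' trace's rate. The baseline is the mean of the valid points in the 1 s
#' pre-onset interval `[-1, 0)` — while the masker is already on — and is
#' subtracted from the whole epoch.
#'
#' Epochs are dropped (with a warning) when the trial extends beyond the
#' trace, when strictly more than `max_removed` of the epoch's points were
#' removed during cleaning (interpolated points count as removed), or when
#' fewer than half of the baseline points are valid.
#'
#' @param trace A cleaned [uniform_trace()] from [preprocess_recording()].
#' @param events Event log data frame (see [read_events()]).
#' @param window Relative window in seconds (default `c(-1, 4)`).
#' @param baseline_window Interval whose valid points define the baseline
#'   (default `c(-1, 0)`, right-open).
#' @param max_removed Epoch exclusion threshold (default 0.5, strict).
#' @return List of `pupil_epoch` objects; each has `rel_time`, `values`
#'   (baseline-corrected), `valid`, `measured` (valid and not
#'   interpolated), `baseline_value`, `removed_fraction` and `trial_id`.
#' @export
epoch_trace <- function(trace, events, window = c(-1, 4),
                        baseline_window = c(-1, 0), max_removed = 0.5) {
  stopifnot(inherits(trace, "uniform_trace"), is.data.frame(events))
  fs <- trace$fs
  rel <- seq(window[1] * fs, window[2] * fs) / fs
  t <- trace_times(trace)
  t_end <- t[length(t)]
  epochs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(events))) {
    onset <- events$sentence_on[i]
    if (onset + window[1] < trace$t0 - 1e-9 ||
        onset + window[2] > t_end + 1e-9) {
      skipped <- c(skipped, sprintf("trial %s (outside trace)",
                                    events$trial_id[i]))
      next
    }
    abs_t <- onset + rel
    vals <- stats::approx(t, trace$values, xout = abs_t, rule = 2)$y
    # a grid point is valid/measured only if both bracketing trace
    # samples are
    lo <- pmin(pmax(floor((abs_t - trace$t0) * fs + 1e-9) + 1L, 1L),
               length(t))
    hi <- pmin(lo + 1L, length(t))
    on_grid <- abs((abs_t - t[lo]) * fs) < 1e-6
    valid <- ifelse(on_grid, trace$valid[lo],
                    trace$valid[lo] & trace$valid[hi])
    measured_mask <- trace$valid & !trace$interpolated
    measured <- ifelse(on_grid, measured_mask[lo],
                       measured_mask[lo] & measured_mask[hi])
    rem <- 1 - mean(measured)
    if (rem > max_removed) {
      skipped <- c(skipped, sprintf("trial %s (%.0f%% removed)",
                                    events$trial_id[i], 100 * rem))
      next
    }
    in_base <- rel >= baseline_window[1] - 1e-9 &
      rel < baseline_window[2] - 1e-9
    base_ok <- valid & in_base
    if (sum(base_ok) < 0.5 * sum(in_base)) {
      skipped <- c(skipped, sprintf("trial %s (baseline too sparse)",
                                    events$trial_id[i]))
      next
    }
    baseline <- mean(vals[base_ok])
    epochs[[length(epochs) + 1L]] <- structure(
      list(rel_time = rel, values = vals - baseline, valid = valid,
           measured = measured, baseline_value = baseline,
           removed_fraction = rem, trial_id = events$trial_id[i]),
      class = "pupil_epoch")
  }
  if (length(skipped)) {
    warning("epochs skipped: ", paste(skipped, collapse = "; "))
  }
  epochs
}

#' Average epochs into a per-condition curve
#'
#' Pointwise mean over the epochs' valid samples, with the per-point SD
#' and the number of contributing epochs recorded (the SD is what the
#' variability "cloud" around a mean curve displays). Points with no
#' contributing epoch are marked invalid.
#'
#' @param epochs Non-empty list of epochs from [epoch_trace()].
#' @param subject,microphone,configuration Optional labels carried along.
#' @return Object of class `condition_curve` with fields `rel_time`,
#'   `mean`, `sd`, `n_per_point`, `valid`, `n_epochs`, plus `ppd` and
#'   `ppd_time` filled in by [peak_pupil_dilation()].
#' @export
average_epochs <- function(epochs, subject = NA_character_,
                           microphone = NA_character_,
                           configuration = NA_character_) {
  if (length(epochs) == 0L) stop("cannot average an empty list of epochs")
  rel <- epochs[[1]]$rel_time
  vals <- vapply(epochs, function(e) ifelse(e$valid, e$values, NA_real_),
                 numeric(length(rel)))
  vals <- matrix(vals, nrow = length(rel))
  n_pt <- rowSums(!is.na(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1, stats::sd, na.rm = TRUE)
  mu[n_pt == 0L] <- NA_real_
  curve <- structure(
    list(subject = subject, microphone = microphone,
         configuration = configuration, rel_time = rel, mean = mu,
         sd = sdv, n_per_point = n_pt, valid = n_pt > 0L,
         n_epochs = length(epochs), ppd = NA_real_, ppd_time = NA_real_),
    class = "condition_curve")
  pk <- tryCatch(peak_pupil_dilation(curve), error = function(e) {
    warning(conditionMessage(e))
    list(ppd = NA_real_, time = NA_real_)
  })
  curve$ppd <- pk$ppd
  curve$ppd_time <- pk$time
  curve
}

#' @export
print.condition_curve <- function(x, ...) {
  cat(sprintf(
    "<condition_curve> %s / %s / %s: %d epochs, PPD %.4f au at %.2f s\n",
    x$subject, x$microphone, x$configuration, x$n_epochs, x$ppd,
    x$ppd_time))
  invisible(x)
}

#' Peak pupil dilation of a condition curve
#'
#' The maximum of the baseline-corrected mean curve over the valid points
#' inside `window` — by default from sentence onset to 4 s after it, the
#' average noise offset. The peak is read from the averaged curve, not
#' from per-trial peaks.
#'
#' @param curve A `condition_curve` from [average_epochs()].
#' @param window Search window in seconds relative to sentence onset
#'   (default `c(0, 4)`).
#' @return List with `ppd` (au) and `time` (s, relative to onset).
#' @export
peak_pupil_dilation <- function(curve, window = c(0, 4)) {
  stopifnot(inherits(curve, "condition_curve"))
  sel <- curve$valid & curve$rel_time >= window[1] - 1e-9 &
    curve$rel_time <= window[2] + 1e-9
  if (!any(sel)) {
    stop(sprintf("no valid curve point in [%g, %g] s for %s / %s / %s",
                 window[1], window[2], curve$subject, curve$microphone,
                 curve$configuration))
  }
  i <- which(sel)[which.max(curve$mean[sel])]
  list(ppd = curve$mean[i], time = curve$rel_time[i])
}

#' Flatten condition curves into a plotting/export table
#'
#' @param curves List of `condition_curve` objects.
#' @return Data frame with one row per curve point: labels, `rel_time`,
#'   `mean`, `sd`, `n`.
#' @export
curves_to_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) {
    data.frame(subject = cu$subject, microphone = cu$microphone,
               configuration = cu$configuration, rel_time = cu$rel_time,
               mean = cu$mean, sd = cu$sd, n = cu$n_per_point,
               stringsAsFactors = FALSE)
  }))
}
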