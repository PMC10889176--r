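#' Construct a simulated listener with a logistic psychometric function
#'
#' A listener is described by the speech-to-noise ratio (or speech level, for
#' quiet testing) at which they repeat 50% of sentences correctly
#' (`srt_true`), the steepness of the psychometric function at that point
#' (`slope`, in probability per dB), and a lapse rate capturing attentional
#' misses and lucky guesses.
#'
#' The probability of a correct repetition at stimulus level `x` is
#'
#' \deqn{p(x) = \lambda/2 + (1 - \lambda)\,
#'   \mathrm{logistic}\{4 s (x - \theta)\}}
#'
#' where \eqn{\theta} is `srt_true`, \eqn{s} is `slope` and \eqn{\lambda} is
#' `lapse`. The `4 s` scaling makes `slope` equal to the derivative of
#' \eqn{p} at the midpoint when `lapse = 0`, and \eqn{p(\theta) = 0.5}
#' for any lapse rate.
#'
#' @param srt_true dB (SNR for noise testing, level for quiet testing) at
#'   which the listener scores 50% correct.
#' @param slope Psychometric slope at the midpoint, probability per dB;
#'   must be positive. Default 0.1/dB, a typical sentence-test slope.
#' @param lapse Lapse rate in `[0, 0.1]`.
#' @return An object of class `listener_profile`.
#' @seealso [psychometric_p()], [simulate_response()], [run_noise_track()]
#' @export
#' @examples
#' l <- listener_profile(srt_true = 2, slope = 0.1)
#' psychometric_p(l, snr = 2)   # 0.5 by construction
listener_profile <- function(srt_true, slope = 0.1, lapse = 0) {
  stopifnot(is.numeric(srt_true), length(srt_true) == 1L, is.finite(srt_true))
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0) {
    stop("`slope` must be a single positive number (probability per dB)")
  }
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse > 0.1) {
    stop("`lapse` must lie in [0, 0.1]")
  }
  structure(list(srt_true = srt_true, slope = slope, lapse = lapse),
            class = "listener_profile")
}

#' @export
print.listener_profile <- function(x, ...) {
  cat(sprintf(
    "<listener_profile> 50%% point %.2f dB, slope %.3f /dB, lapse %.3f\n",
    x$srt_true, x$slope, x$lapse))
  invisible(x)
}

#' Probability of a correct response at a given stimulus level
#'
#' Evaluates the listener's psychometric function (see
#' [listener_profile()] for the functional form).
#'
#' @param listener A [listener_profile()].
#' @param snr Stimulus level(s) in dB (SNR or speech level); vectorised.
#' @return Probability/-ies of a correct sentence repetition.
#' @export
psychometric_p <- function(listener, snr) {
  stopifnot(inherits(listener, "listener_profile"), is.numeric(snr))
  listener$lapse / 2 + (1 - listener$lapse) *
    stats::plogis(4 * listener$slope * (snr - listener$srt_true))
}

#' Simulate a single sentence-repetition response
#'
#' Draws a Bernoulli response from the listener's psychometric function.
#' This stands in for a human scoring sentence repetitions in the adaptive
#' test.
#'
#' @inheritParams psychometric_p
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return Logical: was the sentence repeated correctly?
#' @export
simulate_response <- function(listener, snr, seed = NULL) {
  stopifnot(length(snr) == 1L, is.finite(snr))
  if (!is.null(seed)) set.seed(as.integer(seed))
  stats::runif(1) < psychometric_p(listener, snr)
}
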