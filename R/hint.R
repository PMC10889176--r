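#' Configuration of the adaptive sentence test
#'
#' Parameters of the one-up/one-down adaptive procedure used for
#' HINT-style sentence testing in quiet and in noise. In noise, the target
#' speech is fixed at `speech_level` (dB SPL) and the masker level is
#' adapted: a correct repetition raises the masker (lowering the SNR by
#' `step`), an incorrect one lowers it. In quiet, the speech level itself
#' is adapted, starting from `speech_level` (dB HL). The masker starts
#' `noise_lead` seconds before each sentence and ends `noise_tail` seconds
#' after its offset.
#'
#' @param n_sentences Sentences per list (default 20).
#' @param start_snr Starting SNR in dB for the noise test (default +5).
#' @param speech_level Fixed speech level in noise, and starting level in
#'   quiet (default 65).
#' @param step Adaptive step in dB; must be positive. The test procedure
#'   leaves the step unspecified in most clinical descriptions; 2 dB is the
#'   common choice for sentence material.
#' @param noise_lead,noise_tail Seconds of masker before sentence onset and
#'   after sentence offset (defaults 3 and 4).
#' @param sentence_duration Nominal sentence duration in seconds used for
#'   trial timing (default 3).
#' @param outcome_rule How [track_outcome()] summarises a finished track:
#'   `"mean_from_5"` (mean presented level over sentences 5..n, discarding
#'   the approach phase; default) or `"reversal_mean"` (mean of levels at
#'   response reversals).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(n_sentences = 20, start_snr = 5,
                             speech_level = 65, step = 2,
                             noise_lead = 3, noise_tail = 4,
                             sentence_duration = 3,
                             outcome_rule = c("mean_from_5",
                                              "reversal_mean")) {
  outcome_rule <- match.arg(outcome_rule)
  stopifnot(is.numeric(n_sentences), n_sentences >= 2,
            n_sentences == round(n_sentences),
            is.numeric(start_snr), is.finite(start_snr),
            is.numeric(speech_level), is.finite(speech_level),
            is.numeric(noise_lead), noise_lead >= 0,
            is.numeric(noise_tail), noise_tail >= 0,
            is.numeric(sentence_duration), sentence_duration > 0)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0) {
    stop("`step` must be a single positive number of dB")
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 start_snr = start_snr, speech_level = speech_level,
                 step = step, noise_lead = noise_lead,
                 noise_tail = noise_tail,
                 sentence_duration = sentence_duration,
                 outcome_rule = outcome_rule),
            class = "staircase_config")
}

# Shared one-up/one-down engine over an arbitrary adapted level.
# `direction` is +1 when a correct answer should *decrease* the adapted
# level (noise test: correct -> louder masker -> lower SNR; quiet test:
# correct -> softer speech).
run_staircase <- function(listener, cfg, start_level, seed = NULL,
                          t_start = 0) {
  stopifnot(inherits(listener, "listener_profile") ||
              is.function(listener),
            inherits(cfg, "staircase_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  respond <- if (is.function(listener)) {
    listener   # deterministic scorer / externally supplied responder
  } else {
    function(lv) stats::runif(1) < psychometric_p(listener, lv)
  }
  n <- cfg$n_sentences
  level <- numeric(n)
  correct <- logical(n)
  level[1] <- start_level
  for (i in seq_len(n)) {
    correct[i] <- isTRUE(respond(level[i]))
    if (i < n) {
      level[i + 1] <- level[i] + if (correct[i]) -cfg$step else cfg$step
    }
  }
  trial_len <- cfg$noise_lead + cfg$sentence_duration + cfg$noise_tail
  noise_on <- t_start + (seq_len(n) - 1) * trial_len
  sentence_on <- noise_on + cfg$noise_lead
  sentence_off <- sentence_on + cfg$sentence_duration
  noise_off <- sentence_off + cfg$noise_tail
  track <- list(
    trials = data.frame(trial_id = seq_len(n), snr = level,
                        correct = correct,
                        noise_on = noise_on, sentence_on = sentence_on,
                        sentence_off = sentence_off, noise_off = noise_off),
    config = cfg)
  class(track) <- "staircase_track"
  track$outcome <- track_outcome(track)
  track
}

#' Run an adaptive speech-in-noise track
#'
#' Simulates one list of sentences under the adaptive noise procedure:
#' the first sentence is presented at `start_snr`; after each response the
#' masker level rises by `step` dB on a correct repetition (so the SNR
#' decreases) and falls on an incorrect one. Speech stays fixed at
#' `speech_level`. Trial timing events (noise on/off, sentence on/off) are
#' emitted with the configured lead and tail.
#'
#' @param listener A [listener_profile()] defined over SNR in dB, or a
#'   function mapping a presented level to a logical response — a
#'   deterministic scorer, or a replay of externally scored responses.
#' @param cfg A [staircase_config()].
#' @param seed Optional integer seed for reproducibility.
#' @param t_start Session time (s) at which the first trial's masker starts.
#' @return A `staircase_track`: a list with `trials` (data frame of
#'   `trial_id`, `snr`, `correct` and the four timing columns), `config`,
#'   and `outcome` (the end-of-list SNR in dB, see [track_outcome()]).
#' @export
#' @examples
#' l <- listener_profile(srt_true = 2)
#' tr <- run_noise_track(l, staircase_config(), seed = 1)
#' tr$outcome
run_noise_track <- function(listener, cfg = staircase_config(),
                            seed = NULL, t_start = 0) {
  run_staircase(listener, cfg, start_level = cfg$start_snr,
                seed = seed, t_start = t_start)
}

#' Run an adaptive quiet track (speech reception threshold)
#'
#' Same one-up/one-down logic as [run_noise_track()] applied to the speech
#' presentation level with no masker: the list starts at
#' `cfg$speech_level` and the level is adjusted by `step` after each
#' response. The outcome is the speech reception threshold (SRT), the
#' level at 50% correct repetitions. The `listener` must be defined over
#' speech level (dB HL) rather than SNR.
#'
#' @inheritParams run_noise_track
#' @return A `staircase_track` whose `snr` column holds presented speech
#'   levels and whose `outcome` is the SRT.
#' @export
run_quiet_track <- function(listener, cfg = staircase_config(),
                            seed = NULL, t_start = 0) {
  run_staircase(listener, cfg, start_level = cfg$speech_level,
                seed = seed, t_start = t_start)
}

#' Summarise a finished staircase track into a single level
#'
#' The clinical procedure reports one number per list ("an SNR was
#' calculated at the end of the list") without specifying the estimator.
#' The default discards the approach phase (the first four sentences,
#' during which the track is still descending from its starting level) and
#' averages the presented levels of sentences 5..n. The alternative
#' averages the levels at which the response direction reversed.
#'
#' @param track A `staircase_track`.
#' @param rule `"mean_from_5"` (default, taken from the track's config) or
#'   `"reversal_mean"`.
#' @return The outcome in dB (SNR for noise tracks, SRT for quiet tracks).
#' @export
track_outcome <- function(track, rule = NULL) {
  stopifnot(inherits(track, "staircase_track"))
  if (is.null(rule)) rule <- track$config$outcome_rule
  snr <- track$trials$snr
  n <- length(snr)
  if (rule == "mean_from_5") {
    from <- min(5L, n)
    mean(snr[from:n])
  } else if (rule == "reversal_mean") {
    correct <- track$trials$correct
    rev_idx <- which(diff(correct) != 0) + 1L
    if (length(rev_idx) == 0L) return(mean(snr))
    mean(snr[rev_idx])
  } else {
    stop("unknown outcome rule: ", rule)
  }
}
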