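#' Parameters of the synthetic pupil-signal generator
#'
#' Controls the components of a simulated eye-tracker diameter stream:
#' a subject-specific tonic baseline with slow random-walk drift, a
#' task-evoked dilation pulse per sentence, additive sensor noise, and
#' Poisson-placed blinks during which the measured diameter collapses to
#' zero and the tracker's confidence drops.
#'
#' The evoked pulse is an Erlang-style kernel commonly used for
#' task-evoked pupil responses,
#' \deqn{h(u) = (u/t_p)^{n} \exp\{n (1 - u/t_p)\}, \quad u \ge 0,}
#' with `u` the time since `sentence onset + evoked_latency` and
#' \eqn{t_p = } `evoked_peak_time - evoked_latency`. It is smooth,
#' causal and unimodal with its maximum of exactly 1 at `evoked_peak_time`
#' after sentence onset, so the pulse added to the trace peaks at exactly
#' `evoked_amplitude`.
#'
#' @param fs_raw Raw sampling rate in Hz; must exceed 60 so that
#'   resampling to the 60 Hz analysis grid is a genuine operation.
#' @param baseline_mean Tonic pupil diameter, arbitrary units (au).
#' @param drift_sd Random-walk drift increment SD in au per sqrt(second);
#'   0 disables drift.
#' @param evoked_amplitude Peak height of the task-evoked pulse (au).
#' @param evoked_latency Seconds after sentence onset at which the pulse
#'   departs from zero.
#' @param evoked_peak_time Seconds after sentence onset of the pulse
#'   maximum; must exceed `evoked_latency`.
#' @param kernel_shape Shape parameter `n` of the kernel (default 10, the
#'   conventional pupil-response value).
#' @param noise_sd White sensor noise SD (au).
#' @param blink_rate Blink events per second (Poisson).
#' @param blink_duration_mean Mean blink duration in seconds; individual
#'   durations are gamma-distributed (shape 4) and floored at 50 ms.
#' @return An object of class `pupil_gen_params`.
#' @export
pupil_gen_params <- function(fs_raw = 120, baseline_mean = 4.5,
                             drift_sd = 0.005, evoked_amplitude = 0.052,
                             evoked_latency = 0.2, evoked_peak_time = 2.2,
                             kernel_shape = 10, noise_sd = 0.01,
                             blink_rate = 0.2, blink_duration_mean = 0.15) {
  stopifnot(fs_raw > 60, baseline_mean >= 0, drift_sd >= 0,
            evoked_latency >= 0, evoked_peak_time > evoked_latency,
            kernel_shape > 0, noise_sd >= 0, blink_rate >= 0,
            blink_duration_mean > 0)
  structure(list(fs_raw = fs_raw, baseline_mean = baseline_mean,
                 drift_sd = drift_sd, evoked_amplitude = evoked_amplitude,
                 evoked_latency = evoked_latency,
                 evoked_peak_time = evoked_peak_time,
                 kernel_shape = kernel_shape, noise_sd = noise_sd,
                 blink_rate = blink_rate,
                 blink_duration_mean = blink_duration_mean),
            class = "pupil_gen_params")
}

# Evoked kernel evaluated at absolute times t for a sentence starting at
# `onset`; returns the unit-height pulse (multiply by evoked_amplitude).
evoked_kernel <- function(t, onset, params) {
  u <- t - onset - params$evoked_latency
  tp <- params$evoked_peak_time - params$evoked_latency
  h <- numeric(length(t))
  pos <- u > 0
  n <- params$kernel_shape
  h[pos] <- (u[pos] / tp)^n * exp(n * (1 - u[pos] / tp))
  h
}

#' Study design: subjects, microphone programs and sound configurations
#'
#' The default design mirrors a bimodal cochlear-implant protocol: each
#' subject is tested in quiet (`S0`) and in nine noise conditions, the
#' crossing of three processor microphone programs with three
#' speech/noise spatial configurations (noise co-located, noise on the
#' implant side, noise on the contralateral side) — ten conditions in all.
#'
#' @param n_subjects Number of subjects.
#' @param microphones Character vector of microphone program labels.
#' @param configurations Character vector of noise configuration labels.
#' @param sentences_per_list Sentences per adaptive list (default 20).
#' @param include_quiet Include the quiet (`S0`) condition (default TRUE).
#' @return An object of class `study_design` with a `conditions` data
#'   frame (one row per condition; quiet has microphone `"Speech Omni"`).
#' @export
study_design <- function(n_subjects = 8,
                         microphones = c("Speech Omni", "Opti Omni",
                                         "Split Dir"),
                         configurations = c("S0N0", "S0Nci", "S0Nctr"),
                         sentences_per_list = 20,
                         include_quiet = TRUE) {
  stopifnot(n_subjects >= 1, length(microphones) >= 1,
            length(configurations) >= 1, sentences_per_list >= 2)
  conds <- expand.grid(microphone = microphones,
                       configuration = configurations,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (include_quiet) {
    conds <- rbind(data.frame(microphone = microphones[1],
                              configuration = "S0",
                              stringsAsFactors = FALSE),
                   conds)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 subjects = sprintf("S%02d", seq_len(n_subjects)),
                 microphones = microphones,
                 configurations = configurations,
                 include_quiet = include_quiet,
                 sentences_per_list = as.integer(sentences_per_list),
                 conditions = conds),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d subjects x %d conditions, %d sentences/list\n",
              x$n_subjects, nrow(x$conditions), x$sentences_per_list))
  invisible(x)
}

#' Derive a per-stream seed from the master seed
#'
#' Deterministic seed splitting so that any subject/condition stream can
#' be regenerated in isolation:
#' `(master * 100003 + subject_idx * 211 + condition_idx * 7 + 1)
#' mod (2^31 - 1)`. The result always fits in R's integer range.
#'
#' @param master Master integer seed.
#' @param subject_idx,condition_idx 1-based indices (0 reserved for
#'   population-level draws).
#' @return Derived integer seed.
#' @export
derive_seed <- function(master, subject_idx, condition_idx) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 100003 +
                subject_idx * 211 + condition_idx * 7 + 1) %% m)
}

#' Generate one raw pupil recording segment for a single trial
#'
#' Produces samples at `params$fs_raw` covering `[noise_on, noise_off]`:
#' baseline + random-walk drift + evoked pulse (onset at
#' `sentence_on + evoked_latency`, maximum `evoked_amplitude` at
#' `sentence_on + evoked_peak_time`) + white noise, with Poisson-placed
#' blinks during which the diameter is replaced by 0 and confidence drops
#' below 0.1; elsewhere confidence is 0.98.
#'
#' @param params A [pupil_gen_params()].
#' @param timing List or one-row data frame with `noise_on`,
#'   `sentence_on`, `sentence_off`, `noise_off` (seconds); must satisfy
#'   `noise_on <= sentence_on < sentence_off <= noise_off`.
#' @param seed Optional integer seed.
#' @return A [pupil_recording()] with one sample per 1/`fs_raw` s.
#' @export
#' @examples
#' quiet <- pupil_gen_params(noise_sd = 0, blink_rate = 0, drift_sd = 0)
#' timing <- list(noise_on = 0, sentence_on = 3, sentence_off = 6,
#'                noise_off = 10)
#' rec <- gen_pupil_trial(quiet, timing, seed = 1)
#' max(rec$samples$diameter) - quiet$baseline_mean  # = evoked_amplitude
gen_pupil_trial <- function(params, timing, seed = NULL) {
  stopifnot(inherits(params, "pupil_gen_params"))
  check_trial_timing(timing)
  if (!is.null(seed)) set.seed(as.integer(seed))
  gen_pupil_stream(params, t0 = timing$noise_on, t1 = timing$noise_off,
                   onsets = timing$sentence_on)
}

check_trial_timing <- function(timing) {
  need <- c("noise_on", "sentence_on", "sentence_off", "noise_off")
  if (!all(need %in% names(timing))) {
    stop("timing must provide ", paste(need, collapse = ", "))
  }
  if (!(timing$noise_on <= timing$sentence_on &&
        timing$sentence_on < timing$sentence_off &&
        timing$sentence_off <= timing$noise_off)) {
    stop("invalid trial timing: require noise_on <= sentence_on < ",
         "sentence_off <= noise_off")
  }
  invisible(TRUE)
}

# Core continuous-stream generator shared by gen_pupil_trial (one trial)
# and gen_session (whole list): one draw of drift/noise/blinks over
# [t0, t1] with an evoked pulse per sentence onset. Uses the current RNG
# state; callers set seeds.
gen_pupil_stream <- function(params, t0, t1, onsets) {
  fs <- params$fs_raw
  n <- floor((t1 - t0) * fs + 1e-9) + 1L
  t <- t0 + (seq_len(n) - 1L) / fs
  d <- rep(params$baseline_mean, n)
  if (params$drift_sd > 0) {
    d <- d + cumsum(stats::rnorm(n, 0, params$drift_sd / sqrt(fs)))
  }
  for (on in onsets) {
    d <- d + params$evoked_amplitude * evoked_kernel(t, on, params)
  }
  if (params$noise_sd > 0) d <- d + stats::rnorm(n, 0, params$noise_sd)
  conf <- rep(0.98, n)
  n_blinks <- stats::rpois(1, params$blink_rate * (t1 - t0))
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, t0, t1)
    durs <- pmax(stats::rgamma(n_blinks, shape = 4,
                               scale = params$blink_duration_mean / 4),
                 0.05)
    for (b in seq_len(n_blinks)) {
      in_blink <- t >= starts[b] & t <= starts[b] + durs[b]
      d[in_blink] <- 0
      conf[in_blink] <- 0.02
    }
  }
  d <- pmax(d, 0)
  pupil_recording(data.frame(t = t, diameter = d, confidence = conf))
}

#' Per-subject, per-condition simulation parameters for a whole study
#'
#' Draws one row per subject x condition combining (a) a listener profile
#' whose 50% point is `subject shift + configuration mean + microphone
#' offset` and (b) pupil-generation parameters with a subject-specific
#' evoked amplitude and baseline. Defaults emulate a bimodal
#' cochlear-implant cohort: co-located noise is easiest (mean SNR near
#' 0 dB), spatially separated noise harder (near +3 dB); the directional
#' "Opti Omni" program costs about 1.5 dB relative to the others; peak
#' dilations centre on 0.052 au with no condition effect. Quiet-condition
#' listeners are defined over speech level with a mean SRT of 45 dB HL.
#'
#' @param design A [study_design()].
#' @param config_means Named numeric: mean 50% SNR per configuration (dB).
#' @param mic_offsets Named numeric: additive microphone effects (dB).
#' @param subject_sd Between-subject SD of the SNR shift (dB).
#' @param quiet_srt_mean,quiet_srt_sd Quiet SRT population mean/SD (dB HL).
#' @param slope,lapse Psychometric slope and lapse shared by all listeners.
#' @param ppd_mean,ppd_sd Population mean/SD of the evoked amplitude (au);
#'   draws are floored at 0.02 au.
#' @param baseline_mean,baseline_sd Population mean/SD of tonic diameter.
#' @param pupil_defaults A [pupil_gen_params()] supplying all remaining
#'   generator settings (noise, drift, blinks, kernel).
#' @param seed Integer seed for the population draws.
#' @return Data frame with one row per subject x condition and columns
#'   `subject`, `microphone`, `configuration`, `srt_true`, `slope`,
#'   `lapse`, `evoked_amplitude`, `baseline_mean`.
#' @export
study_parameters <- function(design = study_design(),
                             config_means = c(S0N0 = -0.1, S0Nci = 3.5,
                                              S0Nctr = 3.1),
                             mic_offsets = c("Speech Omni" = -0.7,
                                             "Opti Omni" = 1.0,
                                             "Split Dir" = -0.3),
                             subject_sd = 6, quiet_srt_mean = 45,
                             quiet_srt_sd = 8, slope = 0.1, lapse = 0.02,
                             ppd_mean = 0.052, ppd_sd = 0.012,
                             baseline_mean = 4.5, baseline_sd = 0.5,
                             pupil_defaults = pupil_gen_params(),
                             seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  missing_cfg <- setdiff(design$configurations, names(config_means))
  if (length(missing_cfg)) {
    stop("config_means missing for: ", paste(missing_cfg, collapse = ", "))
  }
  missing_mic <- setdiff(design$microphones, names(mic_offsets))
  if (length(missing_mic)) {
    stop("mic_offsets missing for: ", paste(missing_mic, collapse = ", "))
  }
  set.seed(derive_seed(seed, 0L, 0L))
  ns <- design$n_subjects
  subj_shift <- stats::rnorm(ns, 0, subject_sd)
  subj_quiet <- stats::rnorm(ns, quiet_srt_mean, quiet_srt_sd)
  subj_amp <- pmax(stats::rnorm(ns, ppd_mean, ppd_sd), 0.02)
  subj_base <- pmax(stats::rnorm(ns, baseline_mean, baseline_sd), 1)
  rows <- expand.grid(subject = design$subjects,
                      cond = seq_len(nrow(design$conditions)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conds <- design$conditions[rows$cond, ]
  si <- match(rows$subject, design$subjects)
  srt <- ifelse(conds$configuration == "S0",
                subj_quiet[si],
                subj_shift[si] +
                  unname(config_means[conds$configuration]) +
                  unname(mic_offsets[conds$microphone]))
  out <- data.frame(subject = rows$subject,
                    microphone = conds$microphone,
                    configuration = conds$configuration,
                    srt_true = srt, slope = slope, lapse = lapse,
                    evoked_amplitude = subj_amp[si],
                    baseline_mean = subj_base[si],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pupil_defaults") <- pupil_defaults
  out
}

#' Generate a complete synthetic study dataset on disk
#'
#' For every subject x condition the adaptive track is simulated (noise
#' conditions adapt the masker from +5 dB SNR; the quiet condition adapts
#' the speech level), trial timing is laid out back to back with a fixed
#' inter-trial interval, and one continuous pupil stream covering the
#' whole list is generated with an evoked pulse per sentence. Files
#' follow the package's delimited-text formats (see [read_pupil_csv()],
#' [read_events()], [read_responses()]) plus a YAML manifest recording
#' the design, seed and parameters. Identical seeds yield byte-identical
#' files.
#'
#' @param design A [study_design()].
#' @param params Per-subject/condition parameter table from
#'   [study_parameters()] (any data frame with its columns works).
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed; per-stream seeds are derived with a
#'   fixed splitting rule (see package vignette).
#' @param staircase A [staircase_config()]; `n_sentences` is taken from
#'   the design.
#' @param iti Inter-trial interval in seconds (default 2).
#' @return Invisibly, the manifest as a list.
#' @export
gen_session <- function(design, params, outdir, seed = 1L,
                        staircase = staircase_config(), iti = 2) {
  stopifnot(inherits(design, "study_design"), is.data.frame(params))
  need <- c("subject", "microphone", "configuration", "srt_true",
            "slope", "lapse", "evoked_amplitude", "baseline_mean")
  if (!all(need %in% names(params))) {
    stop("params must have columns: ", paste(need, collapse = ", "))
  }
  pupil_defaults <- attr(params, "pupil_defaults")
  if (is.null(pupil_defaults)) pupil_defaults <- pupil_gen_params()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- staircase
  cfg$n_sentences <- design$sentences_per_list
  files <- list()
  for (s_idx in seq_len(design$n_subjects)) {
    subj <- design$subjects[s_idx]
    ev_all <- list(); resp_all <- list()
    for (c_idx in seq_len(nrow(design$conditions))) {
      mic <- design$conditions$microphone[c_idx]
      conf <- design$conditions$configuration[c_idx]
      row <- params[params$subject == subj & params$microphone == mic &
                      params$configuration == conf, ]
      if (nrow(row) != 1L) {
        stop(sprintf("missing parameters for %s / %s / %s",
                     subj, mic, conf))
      }
      listener <- listener_profile(row$srt_true, row$slope, row$lapse)
      seed_sc <- derive_seed(seed, s_idx, c_idx)
      track <- if (conf == "S0") {
        run_quiet_track(listener, cfg, seed = seed_sc)
      } else {
        run_noise_track(listener, cfg, seed = seed_sc)
      }
      tr <- track$trials
      # back-to-back trials separated by the inter-trial interval
      trial_len <- cfg$noise_lead + cfg$sentence_duration + cfg$noise_tail
      offset <- (tr$trial_id - 1) * (trial_len + iti)
      for (col in c("noise_on", "sentence_on", "sentence_off", "noise_off"))
        tr[[col]] <- tr[[col]] - (tr$trial_id - 1) * trial_len + offset
      pp <- pupil_defaults
      pp$baseline_mean <- row$baseline_mean
      pp$evoked_amplitude <- row$evoked_amplitude
      set.seed(derive_seed(seed_sc, 1L, 0L))
      rec <- gen_pupil_stream(pp, t0 = 0, t1 = max(tr$noise_off),
                              onsets = tr$sentence_on)
      rec$subject <- subj; rec$microphone <- mic; rec$configuration <- conf
      pf <- file.path(outdir, sprintf("pupil_%s_%s_%s.csv", subj,
                                      gsub(" ", "", mic), conf))
      write_pupil_csv(rec, pf)
      files[[length(files) + 1L]] <- list(
        path = basename(pf), role = "pupil_samples", subject = subj,
        microphone = mic, configuration = conf)
      ev_all[[c_idx]] <- data.frame(
        trial_id = tr$trial_id, microphone = mic, configuration = conf,
        noise_on = tr$noise_on, sentence_on = tr$sentence_on,
        sentence_off = tr$sentence_off, noise_off = tr$noise_off,
        snr_presented = tr$snr, stringsAsFactors = FALSE)
      resp_all[[c_idx]] <- data.frame(
        trial_id = tr$trial_id, microphone = mic, configuration = conf,
        snr = tr$snr, correct = as.integer(tr$correct),
        stringsAsFactors = FALSE)
    }
    ef <- file.path(outdir, sprintf("events_%s.csv", subj))
    rf <- file.path(outdir, sprintf("responses_%s.csv", subj))
    write_events(do.call(rbind, ev_all), ef)
    write_responses(do.call(rbind, resp_all), rf)
    files[[length(files) + 1L]] <- list(path = basename(ef),
                                        role = "events", subject = subj)
    files[[length(files) + 1L]] <- list(path = basename(rf),
                                        role = "responses", subject = subj)
  }
  manifest <- list(
    design = list(n_subjects = design$n_subjects,
                  subjects = design$subjects,
                  microphones = design$microphones,
                  configurations = design$configurations,
                  include_quiet = design$include_quiet,
                  sentences_per_list = design$sentences_per_list),
    seed = as.integer(seed),
    seed_rule = "stream seed = (master*100003 + subject*211 + condition*7 + 1) mod (2^31-1)",
    staircase = unclass(cfg), iti = iti,
    pupil_defaults = unclass(pupil_defaults),
    diameter_unit = "au",
    files = files)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
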