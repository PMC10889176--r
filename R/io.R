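#' Construct a raw pupil recording
#'
#' A raw recording is an irregular sample stream of
#' `(t, diameter, confidence)` triples as exported by wearable eye
#' trackers, optionally tagged with subject and condition labels.
#' Timestamps must be strictly increasing, diameters non-negative, and
#' confidence values in `[0, 1]` (out-of-range confidence is clipped with
#' a warning, matching common tracker export quirks).
#'
#' @param samples Data frame with numeric columns `t` (s), `diameter`
#'   (au or mm) and `confidence`.
#' @param subject,microphone,configuration Optional labels.
#' @param diameter_unit Unit string carried as metadata (default "au");
#'   the pipeline itself is unit-agnostic.
#' @return Object of class `pupil_recording`.
#' @export
pupil_recording <- function(samples, subject = NA_character_,
                            microphone = NA_character_,
                            configuration = NA_character_,
                            diameter_unit = "au") {
  need <- c("t", "diameter", "confidence")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    stop("pupil samples missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(samples) == 0L) stop("pupil recording has no samples")
  if (any(!is.finite(samples$t))) stop("non-finite timestamps")
  if (any(diff(samples$t) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (any(samples$diameter < 0, na.rm = TRUE)) {
    stop("negative pupil diameters")
  }
  if (any(samples$confidence < 0 | samples$confidence > 1, na.rm = TRUE)) {
    warning("confidence values outside [0, 1] clipped")
    samples$confidence <- pmin(pmax(samples$confidence, 0), 1)
  }
  structure(list(samples = samples[need], subject = subject,
                 microphone = microphone, configuration = configuration,
                 diameter_unit = diameter_unit),
            class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf(
    "<pupil_recording> %s / %s / %s: %d samples over %.1f s (%s)\n",
    x$subject, x$microphone, x$configuration, nrow(x$samples),
    diff(range(x$samples$t)), x$diameter_unit))
  invisible(x)
}

# Full-precision, locale-independent CSV writer: doubles are written with
# "%.17g" so that read(write(x)) reproduces x bit-for-bit, and output is
# byte-stable across runs.
write_csv_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, need, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  if (file.size(path) == 0L) stop(what, " file is empty: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(what, " file ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop(what, " file has a header but no rows: ", path)
  df
}

#' Read/write a raw pupil sample stream
#'
#' The on-disk dialect is a comma-separated file with a header and
#' columns `t` (seconds), `diameter`, `confidence`, decimal point `"."`
#' regardless of locale. Reading enforces the [pupil_recording()]
#' invariants: strictly increasing time (violations are rejected),
#' confidence clipped to `[0, 1]` with a warning.
#'
#' @param path File path.
#' @param subject,microphone,configuration Optional labels to attach.
#' @return `read_pupil_csv()` returns a [pupil_recording()].
#' @export
read_pupil_csv <- function(path, subject = NA_character_,
                           microphone = NA_character_,
                           configuration = NA_character_) {
  df <- read_csv_checked(path, c("t", "diameter", "confidence"),
                         "pupil samples")
  pupil_recording(df, subject = subject, microphone = microphone,
                  configuration = configuration)
}

#' @rdname read_pupil_csv
#' @param rec A [pupil_recording()].
#' @export
write_pupil_csv <- function(rec, path) {
  stopifnot(inherits(rec, "pupil_recording"))
  write_csv_precise(rec$samples, path)
}

validate_events <- function(df) {
  bad <- which(!(df$noise_on <= df$sentence_on &
                   df$sentence_on < df$sentence_off &
                   df$sentence_off <= df$noise_off))
  if (length(bad)) {
    stop("event log ordering violated for trial(s): ",
         paste(df$trial_id[bad], collapse = ", "),
         " (require noise_on <= sentence_on < sentence_off <= noise_off)")
  }
  df
}

#' Read/write trial event logs
#'
#' One row per trial with columns `trial_id`, `microphone`,
#' `configuration`, `noise_on`, `sentence_on`, `sentence_off`,
#' `noise_off` (seconds) and `snr_presented` (dB; presented speech level
#' for quiet-condition trials). The timing ordering
#' `noise_on <= sentence_on < sentence_off <= noise_off` is enforced on
#' both read and write; under the default protocol the masker leads the
#' sentence by 3 s and trails it by 4 s.
#'
#' @param path File path.
#' @return `read_events()` returns the validated event data frame.
#' @export
read_events <- function(path) {
  df <- read_csv_checked(path, c("trial_id", "microphone", "configuration",
                                 "noise_on", "sentence_on", "sentence_off",
                                 "noise_off", "snr_presented"),
                         "event log")
  validate_events(df)
}

#' @rdname read_events
#' @param events Event data frame as described above.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  write_csv_precise(events, path)
}

#' Read/write staircase response logs
#'
#' One row per sentence with columns `trial_id`, `microphone`,
#' `configuration`, `snr` (presented dB) and `correct` (0/1).
#'
#' @param path File path.
#' @return `read_responses()` returns the response data frame with
#'   `correct` as integer 0/1.
#' @export
read_responses <- function(path) {
  df <- read_csv_checked(path, c("trial_id", "microphone", "configuration",
                                 "snr", "correct"), "response log")
  if (!all(df$correct %in% c(0L, 1L))) {
    stop("response log `correct` column must be 0/1")
  }
  df
}

#' @rdname read_responses
#' @param responses Response data frame.
#' @export
write_responses <- function(responses, path) {
  write_csv_precise(responses, path)
}

#' Read/write the long results table
#'
#' The long table has one row per subject x microphone x configuration
#' with the adaptive-test outcome (`snr`, dB) and the peak pupil dilation
#' (`ppd`, au) plus the number of epochs that survived cleaning
#' (`n_epochs`). This is the input to the repeated-measures statistics.
#'
#' @param path File path.
#' @return `read_long_table()` returns the data frame.
#' @export
read_long_table <- function(path) {
  read_csv_checked(path, c("subject", "microphone", "configuration",
                           "snr", "ppd"), "long table")
}

#' @rdname read_long_table
#' @param table Long-table data frame.
#' @export
write_long_table <- function(table, path) {
  need <- c("subject", "microphone", "configuration", "snr", "ppd")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("long table missing column(s): ", paste(missing, collapse = ", "))
  }
  write_csv_precise(table, path)
}
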