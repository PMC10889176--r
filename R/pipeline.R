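#' Pipeline configuration
#'
#' All tunable parameters of the simulate/preprocess/epoch/analyze
#' pipeline in one round-trippable structure. Defaults follow the study
#' protocol wherever it specifies a value (60 Hz grid, 35/100 ms blink
#' margins, 2.5 SD / 40 ms outlier rule, 50% exclusion, 50 ms smoothing,
#' [-1, 4] s epochs, 20-sentence lists starting at +5 dB SNR with speech
#' at 65 dB SPL, 3 s noise lead / 4 s tail, alpha = 0.05).
#'
#' @param seed Master seed for simulation.
#' @param design A [study_design()].
#' @param staircase A [staircase_config()].
#' @param preprocess A [preprocess_params()].
#' @param epoch_window,baseline_window Epoch and baseline intervals (s).
#' @param alpha Significance level for the statistical battery.
#' @param iti Inter-trial interval used by the simulator (s).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, design = study_design(),
                            staircase = staircase_config(),
                            preprocess = preprocess_params(),
                            epoch_window = c(-1, 4),
                            baseline_window = c(-1, 0),
                            alpha = 0.05, iti = 2) {
  structure(list(seed = as.integer(seed), design = design,
                 staircase = staircase, preprocess = preprocess,
                 epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 alpha = alpha, iti = iti),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  raw <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  d <- raw$design
  design <- study_design(n_subjects = d$n_subjects,
                         microphones = unlist(d$microphones),
                         configurations = unlist(d$configurations),
                         sentences_per_list = d$sentences_per_list,
                         include_quiet = isTRUE(d$include_quiet))
  pipeline_config(
    seed = raw$seed, design = design,
    staircase = do.call(staircase_config,
                        raw$staircase[names(raw$staircase) != "n_sentences"]),
    preprocess = do.call(preprocess_params, raw$preprocess),
    epoch_window = unlist(raw$epoch_window),
    baseline_window = unlist(raw$baseline_window),
    alpha = raw$alpha, iti = raw$iti)
}

config_hash <- function(config, dir) {
  f <- file.path(dir, "config.yaml")
  write_config(config, f)
  unname(tools::md5sum(f))
}

# Prepend a comment header carrying the config hash, then the CSV body.
write_result_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  writeLines(sprintf("# config_md5=%s", hash), con)
  close(con)
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  suppressWarnings(utils::write.table(out, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Simulate a complete study dataset
#'
#' Draws the simulated cohort with [study_parameters()] and writes the
#' full dataset (pupil streams, event logs, response logs, manifest) with
#' [gen_session()]. Fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param ... Passed to [study_parameters()] (population settings).
#' @return Invisibly, the dataset manifest.
#' @export
cmd_simulate <- function(config = pipeline_config(), outdir, ...) {
  params <- study_parameters(design = config$design, seed = config$seed,
                             ...)
  gen_session(config$design, params, outdir, seed = config$seed,
              staircase = config$staircase, iti = config$iti)
}

#' Analyze a study dataset
#'
#' Runs the full analysis on a dataset laid out by [cmd_simulate()] (or
#' hand-assembled in the same formats): every pupil stream is cleaned
#' ([preprocess_recording()]), epoched and averaged
#' ([epoch_trace()], [average_epochs()]); each adaptive track is
#' summarised with [track_outcome()]; the resulting long table feeds the
#' one-way and two-way repeated-measures ANOVAs, Shapiro-Wilk residual
#' checks, Games-Howell post hoc comparisons (at the Bonferroni-adjusted
#' threshold) and the Spearman correlation between SNR and PPD. Result
#' tables are written as CSV with the configuration hash in a comment
#' header; the run is deterministic.
#'
#' @param datadir Directory containing the dataset and `manifest.yaml`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory for result tables.
#' @return Invisibly, a list with the long table, curves, ANOVA tables,
#'   post hoc tables, normality checks and the SNR-PPD correlation.
#' @export
cmd_analyze <- function(datadir, config = pipeline_config(), outdir) {
  manifest_path <- file.path(datadir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    stop("no manifest.yaml found in ", datadir)
  }
  manifest <- yaml::read_yaml(manifest_path)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config, outdir)
  pupil_files <- Filter(function(f) f$role == "pupil_samples",
                        manifest$files)
  rows <- list(); curves <- list()
  log_lines <- c(sprintf("config_md5=%s", hash),
                 sprintf("seed=%d", manifest$seed),
                 sprintf("n_pupil_files=%d", length(pupil_files)))
  for (f in pupil_files) {
    rec <- read_pupil_csv(file.path(datadir, f$path), subject = f$subject,
                          microphone = f$microphone,
                          configuration = f$configuration)
    ev <- read_events(file.path(datadir,
                                sprintf("events_%s.csv", f$subject)))
    ev <- ev[ev$microphone == f$microphone &
               ev$configuration == f$configuration, ]
    resp <- read_responses(file.path(datadir,
                                     sprintf("responses_%s.csv",
                                             f$subject)))
    resp <- resp[resp$microphone == f$microphone &
                   resp$configuration == f$configuration, ]
    trace <- preprocess_recording(rec, config$preprocess, events = ev)
    epochs <- suppressWarnings(
      epoch_trace(trace, ev, window = config$epoch_window,
                  baseline_window = config$baseline_window,
                  max_removed = config$preprocess$max_removed))
    if (length(epochs) == 0L) {
      log_lines <- c(log_lines, sprintf(
        "dropped %s/%s/%s: no epoch survived cleaning", f$subject,
        f$microphone, f$configuration))
      next
    }
    curve <- average_epochs(epochs, subject = f$subject,
                            microphone = f$microphone,
                            configuration = f$configuration)
    curves[[length(curves) + 1L]] <- curve
    track <- structure(list(trials = data.frame(trial_id = resp$trial_id,
                                                snr = resp$snr,
                                                correct = resp$correct == 1L),
                            config = config$staircase),
                       class = "staircase_track")
    rows[[length(rows) + 1L]] <- data.frame(
      subject = f$subject, microphone = f$microphone,
      configuration = f$configuration, snr = track_outcome(track),
      ppd = curve$ppd, n_epochs = curve$n_epochs, stringsAsFactors = FALSE)
  }
  full_table <- do.call(rbind, rows)
  long <- full_table[full_table$configuration != "S0", ]
  results <- list(long_table = full_table, curves = curves, anova = list(),
                  posthoc = list(), normality = list(), correlation = NULL)

  complete <- tryCatch({
    with(long, stopifnot(all(base::table(subject,
                                         paste(configuration,
                                               microphone)) == 1L)))
    TRUE
  }, error = function(e) FALSE)

  for (resp_var in c("snr", "ppd")) {
    for (fac in c("configuration", "microphone")) {
      nm <- paste(resp_var, fac, sep = "_")
      results$anova[[nm]] <- tryCatch(
        rm_anova_oneway(long, resp_var, fac),
        error = function(e) {
          log_lines <<- c(log_lines, sprintf("one-way %s skipped: %s",
                                             nm, conditionMessage(e)))
          NULL
        })
      if (!is.null(results$anova[[nm]])) {
        results$normality[[nm]] <-
          shapiro_wilk(attr(results$anova[[nm]], "residuals"))
      }
    }
    nm2 <- paste0(resp_var, "_twoway")
    if (complete) {
      results$anova[[nm2]] <- rm_anova_twoway_interaction(long, resp_var)
      results$normality[[nm2]] <-
        shapiro_wilk(attr(results$anova[[nm2]], "residuals"))
    } else {
      log_lines <- c(log_lines, sprintf(
        "two-way ANOVA for %s skipped: incomplete subject x cell crossing",
        resp_var))
    }
    # Games-Howell pairwise comparisons for each factor, reported with
    # the Bonferroni-adjusted threshold alongside
    for (fac in c("configuration", "microphone")) {
      groups <- split(long[[resp_var]], long[[fac]])
      gh <- games_howell(groups)
      gh$alpha_bonferroni <- bonferroni_threshold(config$alpha, nrow(gh))
      results$posthoc[[paste(resp_var, fac, sep = "_")]] <- gh
    }
  }
  results$correlation <- spearman_test(long$snr, long$ppd)

  write_result_csv(full_table, file.path(outdir, "long_table.csv"), hash)
  anova_out <- do.call(rbind, lapply(names(results$anova), function(nm) {
    a <- results$anova[[nm]]
    if (is.null(a)) return(NULL)
    cbind(data.frame(model = nm, stringsAsFactors = FALSE),
          as.data.frame(a))
  }))
  write_result_csv(anova_out, file.path(outdir, "anova_tables.csv"), hash)
  ph_out <- do.call(rbind, lapply(names(results$posthoc), function(nm) {
    cbind(data.frame(comparison = nm, stringsAsFactors = FALSE),
          results$posthoc[[nm]])
  }))
  write_result_csv(ph_out, file.path(outdir, "posthoc_tables.csv"), hash)
  write_result_csv(curves_to_table(curves),
                   file.path(outdir, "condition_curves.csv"), hash)
  corr_df <- data.frame(rho = results$correlation$rho,
                        p = results$correlation$p,
                        n = results$correlation$n,
                        method = results$correlation$method,
                        stringsAsFactors = FALSE)
  write_result_csv(corr_df, file.path(outdir, "correlation.csv"), hash)
  norm_out <- do.call(rbind, lapply(names(results$normality), function(nm) {
    data.frame(model = nm, W = results$normality[[nm]]$W,
               p = results$normality[[nm]]$p, stringsAsFactors = FALSE)
  }))
  write_result_csv(norm_out, file.path(outdir, "normality.csv"), hash)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(results)
}

#' Plain-text summary of an analysis
#'
#' Formats the per-configuration and per-microphone means/SDs of SNR and
#' PPD and the two-way ANOVA table, mirroring the usual summary layout of
#' listening-effort studies.
#'
#' @param results Result list from [cmd_analyze()].
#' @return Character vector of report lines (also printed).
#' @export
cmd_report <- function(results) {
  long <- results$long_table
  long <- long[long$configuration != "S0", ]
  lines <- c("Outcome summary (noise conditions)",
             sprintf("%-16s %10s %8s %10s %8s", "group", "SNR mean",
                     "SD", "PPD mean", "SD"))
  for (fac in c("configuration", "microphone")) {
    for (g in sort(unique(long[[fac]]))) {
      sub <- long[long[[fac]] == g, ]
      lines <- c(lines, sprintf("%-16s %+10.2f %8.2f %10.4f %8.4f", g,
                                mean(sub$snr), stats::sd(sub$snr),
                                mean(sub$ppd), stats::sd(sub$ppd)))
    }
  }
  tw <- results$anova$snr_twoway
  if (!is.null(tw)) {
    lines <- c(lines, "", "Two-way repeated-measures ANOVA (SNR)",
               sprintf("%-28s %8s %8s %10s %10s", "term", "num df",
                       "den df", "F", "p"))
    for (i in seq_len(nrow(tw))) {
      lines <- c(lines, sprintf("%-28s %8d %8d %10.4f %10.4f",
                                tw$term[i], tw$num_df[i], tw$den_df[i],
                                tw$F[i], tw$p[i]))
    }
  }
  if (!is.null(results$correlation)) {
    lines <- c(lines, "", sprintf(
      "Spearman SNR vs PPD: rho = %.3f, p = %.3f (n = %d, %s)",
      results$correlation$rho, results$correlation$p,
      results$correlation$n, results$correlation$method))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @rdname cmd_simulate
#' @export
simulate_study <- cmd_simulate

#' @rdname cmd_analyze
#' @export
analyze_study <- cmd_analyze

#' @rdname cmd_report
#' @export
report_study <- cmd_report

#' Plot per-condition mean pupil curves with a variability cloud
#'
#' One panel per sound configuration, one line per microphone program:
#' the across-subject mean of the subject-level mean curves with a
#' +/- 1 SD ribbon. Requires ggplot2.
#'
#' @param curve_table Data frame from [curves_to_table()] (or the
#'   `condition_curves.csv` output).
#' @return A ggplot object.
#' @export
plot_condition_curves <- function(curve_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  agg <- stats::aggregate(mean ~ rel_time + microphone + configuration,
                          data = curve_table, FUN = mean)
  sds <- stats::aggregate(mean ~ rel_time + microphone + configuration,
                          data = curve_table, FUN = stats::sd)
  agg$sd <- sds$mean
  ggplot2::ggplot(agg, ggplot2::aes(x = rel_time, y = mean,
                                    colour = microphone,
                                    fill = microphone)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~configuration) +
    ggplot2::labs(x = "Time relative to sentence onset (s)",
                  y = "Baseline-corrected pupil diameter (au)") +
    ggplot2::theme_minimal()
}
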