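# long-table builder for a complete n x 3 x 3 within-subject design
make_long <- function(n = 8, effect_config = 0, effect_mic = 0,
                      subj_sd = 2, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- c("S0N0", "S0Nci", "S0Nctr")
  mic <- c("Speech Omni", "Opti Omni", "Split Dir")
  g <- expand.grid(subject = sprintf("S%02d", 1:n), configuration = cfg,
                   microphone = mic, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  subj_eff <- rnorm(n, 0, subj_sd)
  g$snr <- subj_eff[match(g$subject, sprintf("S%02d", 1:n))] +
    effect_config * (match(g$configuration, cfg) - 2) +
    effect_mic * (match(g$microphone, mic) - 2) +
    rnorm(nrow(g), 0, noise_sd)
  g$ppd <- rnorm(nrow(g), 0.05, 0.015)
  g
}
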