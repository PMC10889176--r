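test_that("with all variation off the trial trace is the baseline", {
  p <- pupil_gen_params(noise_sd = 0, blink_rate = 0, drift_sd = 0,
                        evoked_amplitude = 0)
  rec <- gen_pupil_trial(p, list(noise_on = 0, sentence_on = 3,
                                 sentence_off = 6, noise_off = 10),
                         seed = 1)
  expect_true(all(rec$samples$diameter == p$baseline_mean))
  expect_true(all(rec$samples$confidence == 0.98))
  # samples cover [noise_on, noise_off] at fs_raw
  expect_equal(nrow(rec$samples), 10 * p$fs_raw + 1)
})

test_that("the evoked pulse peaks at exactly its amplitude and time", {
  p <- pupil_gen_params(noise_sd = 0, blink_rate = 0, drift_sd = 0,
                        evoked_amplitude = 0.05)
  rec <- gen_pupil_trial(p, list(noise_on = 0, sentence_on = 3,
                                 sentence_off = 6, noise_off = 10))
  d <- rec$samples$diameter
  expect_equal(max(d) - p$baseline_mean, 0.05)
  expect_equal(rec$samples$t[which.max(d)], 3 + p$evoked_peak_time)
  # causal: flat before onset + latency
  pre <- rec$samples$t <= 3 + p$evoked_latency
  expect_true(all(d[pre] == p$baseline_mean))
})

test_that("blink counts follow the Poisson expectation", {
  p <- pupil_gen_params(blink_rate = 0.2, noise_sd = 0, drift_sd = 0,
                        evoked_amplitude = 0)
  timing <- list(noise_on = 0, sentence_on = 3, sentence_off = 5,
                 noise_off = 9)
  set.seed(90)
  counts <- replicate(500, {
    rec <- gen_pupil_trial(p, timing)
    # count confidence-drop runs
    r <- rle(rec$samples$confidence < 0.1)
    sum(r$values)
  })
  lambda <- 0.2 * 9
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 500))
  # blink samples collapse the diameter and drop confidence
  set.seed(91)
  rec <- gen_pupil_trial(pupil_gen_params(blink_rate = 2, noise_sd = 0,
                                          drift_sd = 0,
                                          evoked_amplitude = 0), timing)
  blink <- rec$samples$confidence < 0.1
  expect_gt(sum(blink), 0)
  expect_true(all(rec$samples$diameter[blink] == 0))
})

test_that("invalid trial timing and parameters are rejected", {
  p <- pupil_gen_params()
  expect_error(gen_pupil_trial(p, list(noise_on = 0, sentence_on = 3,
                                       sentence_off = 2, noise_off = 10)),
               "timing")
  expect_error(pupil_gen_params(fs_raw = 50))
  expect_error(pupil_gen_params(evoked_peak_time = 0.1,
                                evoked_latency = 0.2))
  expect_error(pupil_gen_params(blink_rate = -1))
})

test_that("the default design yields 1 quiet + 9 noise conditions", {
  d <- study_design()
  expect_equal(d$n_subjects, 8)
  expect_equal(nrow(d$conditions), 10)
  expect_equal(sum(d$conditions$configuration == "S0"), 1)
  d1 <- study_design(n_subjects = 1, microphones = "Speech Omni",
                     configurations = "S0N0", include_quiet = FALSE)
  expect_equal(nrow(d1$conditions), 1)
})

test_that("gen_session writes a complete, reproducible dataset", {
  design <- study_design(n_subjects = 2, microphones = "Speech Omni",
                         configurations = "S0N0", sentences_per_list = 5,
                         include_quiet = TRUE)
  params <- study_parameters(design, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_session(design, params, d1, seed = 42)
  gen_session(design, params, d2, seed = 42)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  # 2 subjects x 2 conditions pupil files + 2 events + 2 responses + manifest
  expect_length(files, 2 * 2 + 2 + 2 + 1)
  for (f in setdiff(files, "manifest.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  ev <- read_events(file.path(d1, "events_S01.csv"))
  expect_equal(nrow(ev), 2 * 5)
  expect_true(all(ev$sentence_on - ev$noise_on == 3))
  resp <- read_responses(file.path(d1, "responses_S01.csv"))
  expect_equal(nrow(resp), 2 * 5)
  # missing parameter rows are a named, actionable error
  expect_error(gen_session(design, params[params$subject != "S02", ],
                           withr::local_tempdir(), seed = 1),
               "S02")
})

test_that("study parameters require settings for every condition", {
  design <- study_design(configurations = c("S0N0", "S0Nx"))
  expect_error(study_parameters(design), "S0Nx")
  expect_error(study_parameters(study_design(microphones = "Weird Mic")),
               "Weird Mic")
})

test_that("derived stream seeds are distinct and within integer range", {
  seeds <- outer(1:12, 1:10,
                 Vectorize(function(s, c) derive_seed(123, s, c)))
  expect_equal(length(unique(as.vector(seeds))), 120)
  expect_true(all(seeds >= 0 & seeds <= .Machine$integer.max))
})
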