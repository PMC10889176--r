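test_that("one-way RM-ANOVA matches a hand-computed decomposition", {
  # 3 subjects x 3 levels toy table, worked by explicit sums of squares
  y <- c(10, 12, 14,   11, 14, 16,   9, 13, 17)
  df <- data.frame(subject = rep(c("a", "b", "c"), each = 3),
                   configuration = rep(c("L1", "L2", "L3"), 3),
                   microphone = "m", snr = y)
  cells <- matrix(y, 3, 3, byrow = TRUE)
  grand <- mean(cells)
  ss_f <- 3 * sum((colMeans(cells) - grand)^2)
  ss_s <- 3 * sum((rowMeans(cells) - grand)^2)
  ss_e <- sum((cells - grand)^2) - ss_f - ss_s
  F_hand <- (ss_f / 2) / (ss_e / 4)
  a <- rm_anova_oneway(df, "snr", "configuration")
  expect_equal(a$F, F_hand)
  expect_equal(a$num_df, 2)
  expect_equal(a$den_df, 4)
  expect_equal(a$p, pf(F_hand, 2, 4, lower.tail = FALSE))
})

test_that("identical condition means per subject give F = 0", {
  df <- data.frame(subject = rep(c("a", "b"), each = 3),
                   configuration = rep(c("x", "y", "z"), 2),
                   microphone = "m", snr = rep(c(3, 7), each = 3))
  a <- rm_anova_oneway(df, "snr", "configuration")
  expect_equal(a$F, 0)
})

test_that("incomplete designs are rejected naming the missing cells", {
  df <- make_long(4, seed = 1)
  df <- df[!(df$subject == "S02" & df$configuration == "S0Nci"), ]
  expect_error(rm_anova_oneway(df, "snr", "configuration"),
               "S02:S0Nci")
  expect_error(rm_anova_twoway_interaction(df, "snr"), "S02")
})

test_that("RM-ANOVA agrees with aov error strata on random data", {
  set.seed(17)
  for (i in 1:10) {
    df <- make_long(8, effect_config = runif(1, 0, 2))
    df$subject <- factor(df$subject)
    df$configuration <- factor(df$configuration)
    df$microphone <- factor(df$microphone)
    a2 <- rm_anova_twoway_interaction(df, "snr")
    fit <- summary(aov(snr ~ configuration * microphone + Error(subject),
                       data = df))[["Error: Within"]][[1]]
    expect_equal(a2$F[2:4], fit[1:3, "F value"], tolerance = 1e-6)
    expect_equal(a2$p[2:4], fit[1:3, "Pr(>F)"], tolerance = 1e-6)
    agg <- aggregate(snr ~ subject + configuration, df, mean)
    a1 <- rm_anova_oneway(df, "snr", "configuration")
    f1 <- summary(aov(snr ~ configuration + Error(subject),
                      data = agg))[["Error: Within"]][[1]]
    expect_equal(a1$F, f1[1, "F value"], tolerance = 1e-6)
    expect_equal(a1$p, f1[1, "Pr(>F)"], tolerance = 1e-6)
  }
})

test_that("two-way table has the pooled-stratum df layout", {
  df <- make_long(8, seed = 2)
  a <- rm_anova_twoway_interaction(df, "snr")
  expect_equal(a$term, c("(Intercept)", "configuration", "microphone",
                         "configuration:microphone"))
  expect_equal(a$num_df, c(1, 2, 2, 4))
  expect_equal(a$den_df, rep(56, 4))
  # constant response: all F = 0
  df$snr <- 1
  a0 <- rm_anova_twoway_interaction(df, "snr")
  expect_true(all(a0$F[2:4] == 0))
})

test_that("per-subject offsets leave the factor F statistics unchanged", {
  df <- make_long(6, effect_config = 1, seed = 3)
  shift <- rnorm(6, 0, 10)
  df2 <- df
  df2$snr <- df$snr + shift[match(df$subject, sprintf("S%02d", 1:6))]
  for (f in c("configuration", "microphone")) {
    expect_equal(rm_anova_oneway(df, "snr", f)$F,
                 rm_anova_oneway(df2, "snr", f)$F, tolerance = 1e-9)
  }
  a <- rm_anova_twoway_interaction(df, "snr")
  b <- rm_anova_twoway_interaction(df2, "snr")
  expect_equal(a$F[2:4], b$F[2:4], tolerance = 1e-9)
})

test_that("Shapiro-Wilk wrapper validates input and detects departures", {
  sw <- shapiro_wilk(qnorm(ppoints(20)))
  expect_gt(sw$W, 0.99)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  set.seed(18)
  rej <- mean(replicate(200, {
    x <- c(rnorm(25, -3, 0.5), rnorm(25, 3, 0.5))  # heavy bimodal
    shapiro_wilk(x)$p < 0.05
  }))
  expect_gte(rej, 0.95)
})

test_that("Games-Howell matches the Welch/studentized-range formulas", {
  # independent re-derivation of each pair from first principles
  set.seed(19)
  g <- list(a = rnorm(8, 0, 1), b = rnorm(12, 1, 3), c = rnorm(6, -1, 0.5))
  gh <- games_howell(g)
  for (r in seq_len(nrow(gh))) {
    x <- g[[gh$group1[r]]]; y <- g[[gh$group2[r]]]
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    se <- sqrt(vx + vy)
    tv <- (mean(x) - mean(y)) / se
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    p <- ptukey(abs(tv) * sqrt(2), 3, df, lower.tail = FALSE)
    expect_equal(gh$diff[r], mean(x) - mean(y), tolerance = 1e-6)
    expect_equal(gh$t[r], tv, tolerance = 1e-6)
    expect_equal(gh$df[r], df, tolerance = 1e-6)
    expect_equal(gh$p[r], p, tolerance = 1e-6)
  }
  # symmetric in group order (signs flip, p identical)
  gh_rev <- games_howell(rev(g))
  expect_equal(sort(gh$p), sort(gh_rev$p), tolerance = 1e-12)
  # identical groups: zero difference, p = 1
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 3, 1, 4))
  gh2 <- games_howell(same)
  expect_equal(gh2$diff[1], 0)
  expect_equal(gh2$p[1], 1)
  expect_error(games_howell(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Bonferroni threshold divides alpha by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 3), 0.05 / 3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("Spearman correlation handles monotone and reversed data", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 6.0)
  expect_equal(spearman_test(x, exp(x))$rho, 1)
  expect_equal(spearman_test(x, -x^3)$rho, -1)
})

test_that("exact Spearman p equals full enumeration of rank orders", {
  # brute-force oracle: all 120 pairings for n = 5
  set.seed(20)
  x <- rnorm(5); y <- rnorm(5)
  s <- spearman_test(x, y)
  expect_equal(s$method, "exact")
  perms <- pupilEffort:::permutations_all(5)
  rho_all <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  p_oracle <- mean(abs(rho_all) >= abs(s$rho) - 1e-12)
  expect_equal(s$p, p_oracle)
  expect_equal(nrow(perms), 120)
  # agrees with the reference implementation in base R
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ct$estimate))
  expect_equal(s$p, ct$p.value)
  # ties or large n fall back to the t approximation
  st <- spearman_test(c(1, 1, 2, 3, 4), c(2, 1, 4, 3, 5))
  expect_equal(st$method, "t-approximation")
  sl <- spearman_test(rnorm(30), rnorm(30))
  expect_equal(sl$method, "t-approximation")
  expect_error(spearman_test(1:2, 2:3), "at least 3")
})

test_that("pure tone average is the mean of the four thresholds", {
  expect_equal(pure_tone_average(c(40, 40, 40, 40)), 40)
  expect_equal(pure_tone_average(c(35, 45, 40, 60)), 45)
  expect_equal(pure_tone_average(c(30, 40, 50, 60)), 45)
  expect_error(pure_tone_average(c(30, 40, 50)), "four")
})
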