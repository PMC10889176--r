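#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA for a long table of per-subject outcomes.
#' When the table carries both crossed factors, the response is first
#' averaged over the other factor so that every subject contributes one
#' value per level of `factor`. The decomposition is the classical
#' within-subject one: `SS_factor` (df `k - 1`), `SS_subject`
#' (df `n - 1`) and their interaction as error (df `(k - 1)(n - 1)`),
#' with `F = MS_factor / MS_error`. No sphericity correction is applied.
#'
#' @param table Long data frame with columns `subject`, `configuration`,
#'   `microphone` and the response; quiet (`S0`) rows should be excluded
#'   before calling.
#' @param response Response column name, `"snr"` or `"ppd"`.
#' @param factor Within-subject factor, `"configuration"` or
#'   `"microphone"`.
#' @return Object of class `anova_table`: data frame with columns `term`,
#'   `num_df`, `den_df`, `F`, `p`, with the cell residuals in
#'   `attr(, "residuals")` for normality checks.
#' @export
rm_anova_oneway <- function(table, response, factor) {
  stopifnot(is.data.frame(table), response %in% names(table),
            factor %in% names(table), "subject" %in% names(table))
  y_raw <- table[[response]]
  subj <- as.character(table$subject)
  lev <- as.character(table[[factor]])
  cells <- tapply(y_raw, list(subj, lev), mean)
  if (anyNA(cells)) {
    miss <- which(is.na(cells), arr.ind = TRUE)
    stop("incomplete design; missing subject x level cell(s): ",
         paste(sprintf("%s:%s", rownames(cells)[miss[, 1]],
                       colnames(cells)[miss[, 2]]), collapse = ", "))
  }
  n <- nrow(cells); k <- ncol(cells)
  if (k < 2L || n < 2L) stop("need at least 2 subjects and 2 levels")
  grand <- mean(cells)
  lvl_m <- colMeans(cells)
  sub_m <- rowMeans(cells)
  ss_f <- n * sum((lvl_m - grand)^2)
  ss_s <- k * sum((sub_m - grand)^2)
  ss_t <- sum((cells - grand)^2)
  ss_e <- ss_t - ss_f - ss_s
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_e <- ss_e / df2
  Fv <- if (ms_e > 0) (ss_f / df1) / ms_e else 0
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  resid <- sweep(sweep(cells, 1, sub_m), 2, lvl_m) + grand
  out <- data.frame(term = factor, num_df = df1, den_df = df2,
                    F = Fv, p = p, stringsAsFactors = FALSE)
  attr(out, "ss") <- c(factor = ss_f, subject = ss_s, error = ss_e)
  attr(out, "residuals") <- as.numeric(resid)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Two-way repeated-measures ANOVA with interaction
#'
#' Fits the within-subject interaction model for a complete subject x
#' configuration x microphone table (one observation per cell): a subject
#' term plus the two factors and their interaction, with a single pooled
#' residual stratum. For `n` subjects and an `a x b` factorial this gives
#' numerator dfs `1, a-1, b-1, (a-1)(b-1)` and a common denominator df
#' `(n-1)(ab-1)` — 56 for eight subjects in a 3 x 3 design. All F
#' statistics, including the intercept row (which tests the grand mean
#' against the pooled within-subject error), use that stratum, mirroring
#' the mixed-model ANOVA layout common in this literature.
#'
#' @param table Long data frame with `subject`, `configuration`,
#'   `microphone` and the response; exactly one row per cell.
#' @param response Response column name, `"snr"` or `"ppd"`.
#' @return An `anova_table` with rows `(Intercept)`, `configuration`,
#'   `microphone`, `configuration:microphone`; residuals of the full
#'   model are in `attr(, "residuals")`.
#' @export
rm_anova_twoway_interaction <- function(table, response) {
  stopifnot(is.data.frame(table), response %in% names(table))
  y <- table[[response]]
  subj <- as.character(table$subject)
  fa <- as.character(table$configuration)
  fb <- as.character(table$microphone)
  cell_lab <- paste(fa, fb, sep = "\r")
  cells <- tapply(y, list(subj, cell_lab), mean)
  counts <- base::table(subj, cell_lab)
  if (anyNA(cells) || any(counts != 1L)) {
    miss <- which(is.na(cells), arr.ind = TRUE)
    stop("two-way RM-ANOVA needs exactly one observation per subject x ",
         "configuration x microphone cell; missing/duplicated: ",
         if (nrow(miss)) paste(sprintf(
           "%s:%s", rownames(cells)[miss[, 1]],
           gsub("\r", "/", colnames(cells)[miss[, 2]])), collapse = ", ")
         else "duplicated cells present")
  }
  a <- length(unique(fa)); b <- length(unique(fb))
  n <- length(unique(subj))
  if (a < 2L || b < 2L || n < 2L) {
    stop("need at least 2 subjects and 2 levels of each factor")
  }
  cell_m <- tapply(y, list(fa, fb), mean)       # a x b matrix
  grand <- mean(y)
  am <- rowMeans(cell_m); bm <- colMeans(cell_m)
  sub_m <- tapply(y, subj, mean)
  ss_a <- n * b * sum((am - grand)^2)
  ss_b <- n * a * sum((bm - grand)^2)
  ss_ab <- n * sum((cell_m - outer(am, rep(1, b)) -
                      outer(rep(1, a), bm) + grand)^2)
  ss_s <- a * b * sum((sub_m - grand)^2)
  ss_t <- sum((y - grand)^2)
  ss_e <- ss_t - ss_a - ss_b - ss_ab - ss_s
  df_e <- (n - 1L) * (a * b - 1L)
  ms_e <- ss_e / df_e
  ss_int0 <- length(y) * grand^2
  terms <- data.frame(
    term = c("(Intercept)", "configuration", "microphone",
             "configuration:microphone"),
    num_df = c(1L, a - 1L, b - 1L, (a - 1L) * (b - 1L)),
    den_df = df_e,
    ss = c(ss_int0, ss_a, ss_b, ss_ab),
    stringsAsFactors = FALSE)
  terms$F <- if (ms_e > 0) (terms$ss / terms$num_df) / ms_e else 0
  terms$p <- stats::pf(terms$F, terms$num_df, terms$den_df,
                       lower.tail = FALSE)
  fitted <- sub_m[subj] + cell_m[cbind(fa, fb)] - grand
  out <- terms[c("term", "num_df", "den_df", "F", "p")]
  attr(out, "ss") <- stats::setNames(terms$ss, terms$term)
  attr(out, "residuals") <- as.numeric(y - fitted)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Shapiro-Wilk normality test
#'
#' Validating wrapper around [stats::shapiro.test()], used on ANOVA
#' residuals to check the normality assumption.
#'
#' @param residuals Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  }
  if (stats::sd(residuals) == 0) {
    stop("Shapiro-Wilk undefined for a constant sample")
  }
  ht <- stats::shapiro.test(residuals)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Pairwise mean comparisons robust to unequal variances: each pair uses
#' a Welch standard error and Welch-Satterthwaite degrees of freedom, and
#' the p-value comes from the studentized-range distribution with the
#' total number of groups, i.e. `p = P(q_{k,df} >= |t| * sqrt(2))`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations and, unless comparisons are degenerate, positive
#'   variance).
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of group1 minus group2), `se`, `t`, `df`, `p`.
#' @export
games_howell <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    vn1 <- vars[i1] / ns[i1]; vn2 <- vars[i2] / ns[i2]
    se <- sqrt(vn1 + vn2)
    if (se == 0) {
      stop("zero pooled variance between groups '", names(groups)[i1],
           "' and '", names(groups)[i2], "'")
    }
    df <- (vn1 + vn2)^2 /
      (vn1^2 / (ns[i1] - 1L) + vn2^2 / (ns[i2] - 1L))
    tv <- (means[i1] - means[i2]) / se
    p <- stats::ptukey(abs(tv) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = names(groups)[i1], group2 = names(groups)[i2],
               diff = means[i1] - means[i2], se = se, t = tv, df = df,
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Familywise level (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(is.numeric(m), m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

# All permutations of 1:n as an n! x n integer matrix, built iteratively
# (insertion construction). Intended for the exact Spearman null; n <= 10.
permutations_all <- function(n) {
  p <- matrix(1L, 1L, 1L)
  for (m in 2:n) {
    nm <- nrow(p)
    out <- matrix(0L, nm * m, m)
    for (pos in seq_len(m)) {
      rows <- ((pos - 1L) * nm + 1L):(pos * nm)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- p[, seq_len(pos - 1L)]
      out[rows, pos] <- m
      if (pos < m) out[rows, (pos + 1L):m] <- p[, pos:(m - 1L)]
    }
    p <- out
  }
  p
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Rank correlation with midranks for ties. The two-sided p-value uses
#' the exact permutation distribution (full enumeration of all `n!` rank
#' orders) when `n <= 10` and the data are tie-free, and the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df
#' otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Spearman correlation undefined for constant ranks")
  }
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 10L && !ties) {
    perms <- permutations_all(n)
    # null: all pairings of ranks equally likely; rho for each pairing
    denom <- n * (n^2 - 1)
    s <- colSums((t(perms) - seq_len(n))^2)
    rho_null <- 1 - 6 * s / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Pure tone average (PTA)
#'
#' Arithmetic mean of the audiometric thresholds at 500, 1000, 2000 and
#' 4000 Hz.
#'
#' @param thresholds Numeric vector of the four thresholds in dB HL (in
#'   that frequency order).
#' @return PTA in dB HL.
#' @export
pure_tone_average <- function(thresholds) {
  if (length(thresholds) != 4L || any(!is.finite(thresholds))) {
    stop("need the four thresholds at 500/1000/2000/4000 Hz")
  }
  mean(thresholds)
}
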