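#' Summary statistics for one group
#' @param x Numeric vector (n >= 2), NAs dropped.
#' @return List with `n`, `mean`, `sd` (n-1 denominator).
#' @export
summary_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stopf("need at least 2 observations")
  list(n = length(x), mean = mean(x), sd = stats::sd(x))
}

#' Normality screen by adjusted skewness and excess kurtosis
#'
#' Sample-size-adjusted (Fisher-Pearson) skewness and excess kurtosis, the
#' statistics printed by mainstream stats packages, gated by the screening
#' rule used for these data: pass iff |skew| <= 1 and |excess kurtosis| <= 2.
#'
#' @param x Numeric vector, n >= 4, non-constant.
#' @param skew_limit,kurt_limit Pass thresholds (defaults 1 and 2).
#' @return List with `skew`, `kurtosis` (excess) and `pass`.
#' @export
skew_kurtosis_check <- function(x, skew_limit = 1, kurt_limit = 2) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stopf("need at least 4 observations")
  s <- stats::sd(x)
  if (s == 0) stopf("constant vector: skew/kurtosis undefined")
  z <- (x - mean(x)) / s
  skew <- n / ((n - 1) * (n - 2)) * sum(z^3)
  kurt <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  list(skew = skew, kurtosis = kurt,
       pass = abs(skew) <= skew_limit && abs(kurt) <= kurt_limit)
}

#' Square-root transform
#'
#' The variance-reducing transform applied to the (right-skewed, floor-10)
#' PANAS-NA scores before they enter the moderation model.
#'
#' @param x Non-negative numeric vector (NAs passed through).
#' @return Element-wise square root.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stopf("sqrt_transform requires non-negative input")
  sqrt(x)
}

#' Levene's test of equality of variances (mean-centered)
#'
#' One-way ANOVA on the absolute deviations from each group's mean, the
#' classical (mean-centered) form.
#'
#' @param a,b Numeric vectors, each n >= 2 (NAs dropped).
#' @return List with `W` (the F statistic), `df` (c(1, n-2)) and `p`.
#' @export
levene_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  da <- abs(a - mean(a)); db <- abs(b - mean(b))
  d <- c(da, db)
  if (stats::sd(d) == 0) stopf("degenerate input: all absolute deviations equal")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  gm <- mean(d)
  ssb <- n1 * (mean(da) - gm)^2 + n2 * (mean(db) - gm)^2
  ssw <- sum((da - mean(da))^2) + sum((db - mean(db))^2)
  W <- (ssb / 1) / (ssw / (n - 2))
  list(W = W, df = c(1, n - 2), p = stats::pf(W, 1, n - 2, lower.tail = FALSE))
}

#' Two-sample t-test from summary statistics
#'
#' Student (pooled-variance) or Welch (Satterthwaite) t-test computed from
#' group summaries, with `t = (mean1 - mean2)/SE`. Cohen's d is always the
#' pooled-SD standardized difference, whichever t variant is used.
#'
#' @param g1,g2 Group summaries ([summary_stats()] or lists with `n`, `mean`,
#'   `sd`).
#' @param variant `"student"` or `"welch"`.
#' @return A list of class `ttest_result`: `t`, `df`, `p` (two-sided),
#'   `variant`, `cohens_d` (signed, pooled SD).
#' @export
t_from_summary <- function(g1, g2, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (g1$sd == 0 && g2$sd == 0) stopf("both group SDs are zero")
  n1 <- g1$n; n2 <- g2$n
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / (n1 + n2 - 2)
  d <- (g1$mean - g2$mean) / sqrt(sp2)
  if (variant == "student") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- g1$sd^2 / n1; v2 <- g2$sd^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (g1$mean - g2$mean) / se
  structure(list(t = tt, df = df,
                 p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
                 variant = variant, cohens_d = d),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t(%.3f) = %.3f, p = %.4f, d = %.3f\n",
              x$variant, x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Compare two groups with a variance-screened t-test
#'
#' Runs the mean-centered Levene test; if its p-value falls below `alpha`
#' the Welch t-test is used, otherwise the Student pooled test — the
#' equal-variance gate applied throughout the analysis. The chosen path is
#' recorded in the result.
#'
#' @param a,b Numeric vectors (group 1, group 2); NAs dropped.
#' @param alpha Gate level for the Levene screen (default 0.05).
#' @return A `ttest_result` with extra fields `levene_W`, `levene_p`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  lev <- levene_test(a, b)
  variant <- if (lev$p < alpha) "welch" else "student"
  res <- t_from_summary(summary_stats(a), summary_stats(b), variant)
  res$levene_W <- lev$W
  res$levene_p <- lev$p
  res
}
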