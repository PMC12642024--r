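# Heteroscedasticity-consistent covariance of OLS coefficients.
# HC0: e^2; HC1: e^2 * n/(n-k); HC2: e^2/(1-h); HC3: e^2/(1-h)^2.
hc_vcov <- function(X, resid, type = c("HC3", "HC2", "HC1", "HC0")) {
  type <- match.arg(type)
  n <- nrow(X); k <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  h <- rowSums((X %*% XtXi) * X)
  w <- switch(type,
              HC0 = resid^2,
              HC1 = resid^2 * n / (n - k),
              HC2 = resid^2 / (1 - h),
              HC3 = resid^2 / (1 - h)^2)
  XtXi %*% crossprod(X * w, X) %*% XtXi
}

ols_step <- function(X, y, hc_type) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("singular design: predictors are collinear")
  b <- qr.coef(qrX, y)
  fitted <- drop(X %*% b)
  resid <- y - fitted
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  V <- hc_vcov(X, resid, hc_type)
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  df <- nrow(X) - ncol(X)
  tval <- b / se
  sdy <- stats::sd(y)
  beta <- b * apply(X, 2, stats::sd) / sdy   # realized-column convention
  beta[1] <- NA_real_
  list(b = b, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       beta = beta, r2 = r2, vcov = V, df = df, resid = resid)
}

#' Two-step moderation regression with robust standard errors
#'
#' Hierarchical OLS of an outcome (PSE or slope) on social-anxiety status
#' and transformed negative affect. Step 1 fits `y ~ sa + na_c`; Step 2 adds
#' the product `sa * na_c`, where `na_c` is `na` centered at its
#' complete-case mean and `sa` stays 0/1 (0 = LSA, 1 = HSA). Rows with
#' missing `na` are removed listwise. Point estimates are ordinary least
#' squares; standard errors are heteroscedasticity-consistent (HC3 by
#' default, switchable HC0--HC3) in both steps. The increment test is
#' \deqn{F_{change} = \Delta R^2 (n - 4) / (1 - R^2_2)} on (1, n - 4) df.
#'
#' Two standardized-coefficient conventions are reported: `beta` scales each
#' coefficient by the SD of its realized design column (macro-style; the
#' interaction uses the SD of the realized product), and `beta_fullstd`
#' refits on z-scored y/na with the product rebuilt from z-scored components.
#'
#' @param y Outcome vector.
#' @param sa 0/1 social-anxiety indicator (0 = LSA, 1 = HSA).
#' @param na Transformed negative affect (square-root scale); may contain NA.
#' @param hc_type Robust covariance flavor, `"HC3"` (default) to `"HC0"`.
#' @return An object of class `moderation_result` with `step1`, `step2`
#'   (coefficient tables + R^2), `delta_r2`, `f_change`, `df_change`,
#'   `p_change`, `n_used`, `sd_na` (SD of centered na), `sd_y`, `hc_type`.
#' @export
fit_hierarchical <- function(y, sa, na, hc_type = "HC3") {
  keep <- stats::complete.cases(y, sa, na)
  y <- y[keep]; sa <- sa[keep]; na <- na[keep]
  n <- length(y)
  if (n < 8) stopf("need at least 8 complete cases (got %d)", n)
  if (length(unique(sa)) < 2) stopf("singular design: sa has a single level")
  if (!all(sa %in% c(0, 1))) stopf("sa must be coded 0/1")
  na_c <- na - mean(na)

  X1 <- cbind(intercept = 1, sa = sa, na = na_c)
  X2 <- cbind(X1, sa_x_na = sa * na_c)
  s1 <- ols_step(X1, y, hc_type)
  s2 <- ols_step(X2, y, hc_type)

  fullstd <- function(X) {
    zy <- as.vector(scale(y)); zsa <- as.vector(scale(sa)); zna <- as.vector(scale(na_c))
    Z <- cbind(intercept = 1, sa = zsa, na = zna)
    if (ncol(X) == 4) Z <- cbind(Z, sa_x_na = zsa * zna)
    bb <- qr.coef(qr(Z), zy)
    bb[1] <- NA_real_
    bb
  }
  step_table <- function(s, X) {
    data.frame(term = colnames(X), b = unname(s$b), se_robust = unname(s$se),
               beta = unname(s$beta), beta_fullstd = unname(fullstd(X)),
               t = unname(s$t), p = unname(s$p), stringsAsFactors = FALSE)
  }
  delta_r2 <- s2$r2 - s1$r2
  f_change <- delta_r2 * (n - 4) / (1 - s2$r2)
  structure(list(
    step1 = list(coefficients = step_table(s1, X1), r2 = s1$r2, df = s1$df),
    step2 = list(coefficients = step_table(s2, X2), r2 = s2$r2, df = s2$df),
    delta_r2 = delta_r2, f_change = f_change, df_change = c(1, n - 4),
    p_change = stats::pf(f_change, 1, n - 4, lower.tail = FALSE),
    n_used = n, sd_na = stats::sd(na_c), sd_y = stats::sd(y),
    hc_type = hc_type, vcov2 = s2$vcov, b2 = s2$b),
    class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("Moderation (n = %d, %s robust SEs)\n", x$n_used, x$hc_type))
  cat(sprintf("Step 1: R^2 = %.4f\n", x$step1$r2))
  print(x$step1$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("Step 2: R^2 = %.4f, dR^2 = %.4f, F(%d, %d) = %.3f, p = %.4f\n",
              x$step2$r2, x$delta_r2, x$df_change[1], x$df_change[2],
              x$f_change, x$p_change))
  print(x$step2$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simple slopes of the social-anxiety effect at low/high negative affect
#'
#' Pick-a-point probe of the interaction: the SA group difference evaluated
#' at moderator values one SD below and above the mean,
#' \eqn{b_{sa} + b_{int} m} with robust variance
#' \eqn{V[sa] + m^2 V[int] + 2 m\,Cov[sa, int]}, t on n - 4 df.
#'
#' @param result A `moderation_result` from [fit_hierarchical()].
#' @return A `data.frame` with rows at `mean - 1 SD` and `mean + 1 SD`:
#'   `level`, `na_c`, `estimate`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(result) {
  m <- c(-1, 1) * result$sd_na
  b <- result$b2
  V <- result$vcov2
  est <- b["sa"] + b["sa_x_na"] * m
  se <- sqrt(V["sa", "sa"] + m^2 * V["sa_x_na", "sa_x_na"] +
               2 * m * V["sa", "sa_x_na"])
  tt <- est / se
  df <- result$n_used - 4
  data.frame(level = c("mean - 1 SD", "mean + 1 SD"), na_c = m,
             estimate = unname(est), se = unname(se), t = unname(tt),
             p = unname(2 * stats::pt(abs(tt), df, lower.tail = FALSE)),
             stringsAsFactors = FALSE)
}

#' Model-implied outcome surface over group and moderator levels
#'
#' Fitted Step-2 outcome at the four cells `sa` in \{0, 1\} crossed with
#' centered negative affect at -1 SD and +1 SD — the values an interaction
#' plot displays.
#'
#' @param result A `moderation_result`.
#' @return A `data.frame` with columns `sa`, `na_c`, `fitted`.
#' @export
predict_surface <- function(result) {
  grid <- expand.grid(sa = c(0, 1), na_c = c(-1, 1) * result$sd_na)
  b <- result$b2
  grid$fitted <- b["intercept"] + b["sa"] * grid$sa + b["na"] * grid$na_c +
    b["sa_x_na"] * grid$sa * grid$na_c
  grid
}

# Flatten a moderation_result into the report's Table-3/4-shaped rows.
moderation_table <- function(result) {
  s1 <- result$step1$coefficients
  s2 <- result$step2$coefficients
  rows <- rbind(
    data.frame(model = "model1", s1, r2 = result$step1$r2,
               delta_r2 = NA_real_, stringsAsFactors = FALSE),
    data.frame(model = "model2", s2, r2 = result$step2$r2,
               delta_r2 = result$delta_r2, stringsAsFactors = FALSE))
  rows
}
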