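# A small deterministic dataset with both groups and a spread of moderator
# values, used by several blocks below.
micro_data <- function() {
  sa <- rep(c(0, 1), each = 6)
  na <- c(3.2, 3.5, 3.1, 3.9, 3.4, 3.6, 3.8, 4.1, 3.3, 3.7, 4.4, 3.5)
  y <- c(1.2, -0.5, 2.1, 4.0, 0.3, 1.8, 6.2, 9.1, 2.4, 5.5, 12.0, 4.1)
  list(y = y, sa = sa, na = na)
}

test_that("coefficients solve the normal equations (matrix-algebra oracle)", {
  d <- micro_data()
  fit <- fit_hierarchical(d$y, d$sa, d$na)
  na_c <- d$na - mean(d$na)
  X <- cbind(1, d$sa, na_c, d$sa * na_c)
  b_oracle <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$step2$coefficients$b, as.vector(b_oracle), tolerance = 1e-10)

  X1 <- X[, 1:3]
  b1_oracle <- solve(t(X1) %*% X1, t(X1) %*% d$y)
  expect_equal(fit$step1$coefficients$b, as.vector(b1_oracle), tolerance = 1e-10)

  # robust covariance vs a direct sandwich computation (HC3)
  e <- d$y - X %*% b_oracle
  XtXi <- solve(t(X) %*% X)
  h <- diag(X %*% XtXi %*% t(X))
  meat <- t(X) %*% diag(as.vector(e)^2 / (1 - h)^2) %*% X
  V_oracle <- XtXi %*% meat %*% XtXi
  expect_equal(fit$step2$coefficients$se_robust, unname(sqrt(diag(V_oracle))),
               tolerance = 1e-10)
})

test_that("an exact linear outcome yields R^2 = 1 and consistent increments", {
  d <- micro_data()
  na_c <- d$na - mean(d$na)
  y <- 2 + 3 * d$sa - 1.5 * na_c + 4 * d$sa * na_c
  fit <- fit_hierarchical(y, d$sa, d$na)
  expect_equal(fit$step2$r2, 1, tolerance = 1e-12)
  expect_equal(fit$delta_r2, 1 - fit$step1$r2, tolerance = 1e-12)
  b <- fit$step2$coefficients$b
  expect_equal(b, c(2, 3, -1.5, 4), tolerance = 1e-9)
})

test_that("simple slopes obey their defining identity and the re-centering oracle", {
  d <- micro_data()
  fit <- fit_hierarchical(d$y, d$sa, d$na)
  ss <- simple_slopes(fit)
  b <- fit$step2$coefficients$b
  expect_equal(ss$estimate, b[2] + b[4] * c(-1, 1) * fit$sd_na, tolerance = 1e-12)

  # re-centering identity: refit with na centered at mean +/- SD; the sa
  # coefficient and its robust SE must equal the simple slope and its SE
  na_c <- d$na - mean(d$na)
  for (j in 1:2) {
    m <- c(-1, 1)[j] * fit$sd_na
    shifted <- na_c - m
    X <- cbind(1, d$sa, shifted, d$sa * shifted)
    b_r <- solve(t(X) %*% X, t(X) %*% d$y)
    e <- as.vector(d$y - X %*% b_r)
    XtXi <- solve(t(X) %*% X)
    h <- diag(X %*% XtXi %*% t(X))
    V <- XtXi %*% (t(X) %*% diag(e^2 / (1 - h)^2) %*% X) %*% XtXi
    expect_equal(ss$estimate[j], unname(b_r[2, 1]), tolerance = 1e-10)
    expect_equal(ss$se[j], sqrt(V[2, 2]), tolerance = 1e-10)
  }
})

test_that("delta R^2 is invariant to the moderator's centering constant", {
  d <- micro_data()
  f1 <- fit_hierarchical(d$y, d$sa, d$na)
  f2 <- fit_hierarchical(d$y, d$sa, d$na + 11.3)
  expect_equal(f1$delta_r2, f2$delta_r2, tolerance = 1e-12)
  expect_equal(f1$f_change, f2$f_change, tolerance = 1e-12)
  expect_equal(f1$step2$r2, f2$step2$r2, tolerance = 1e-12)
})

test_that("predict_surface is the linear predictor at the four probe cells", {
  d <- micro_data()
  fit <- fit_hierarchical(d$y, d$sa, d$na)
  surf <- predict_surface(fit)
  b <- fit$step2$coefficients$b
  expect_equal(surf$fitted,
               b[1] + b[2] * surf$sa + b[3] * surf$na_c + b[4] * surf$sa * surf$na_c,
               tolerance = 1e-12)
  expect_equal(nrow(surf), 4)
  # a crossing pattern (group gap differing across moderator levels) needs b4
  gap_lo <- surf$fitted[surf$sa == 1 & surf$na_c < 0] - surf$fitted[surf$sa == 0 & surf$na_c < 0]
  gap_hi <- surf$fitted[surf$sa == 1 & surf$na_c > 0] - surf$fitted[surf$sa == 0 & surf$na_c > 0]
  expect_equal(gap_hi - gap_lo, b[4] * 2 * fit$sd_na, tolerance = 1e-12)
})

test_that("degenerate inputs raise informative errors", {
  d <- micro_data()
  expect_error(fit_hierarchical(d$y, rep(1, 12), d$na), "single level")
  expect_error(fit_hierarchical(d$y[1:6], d$sa[1:6], d$na[1:6]), "8 complete cases")
  expect_error(fit_hierarchical(d$y, d$sa, rep(2, 12)), "singular|collinear")
})

test_that("rows with missing moderator are dropped listwise", {
  d <- micro_data()
  na <- d$na; na[c(2, 9)] <- NA
  fit <- fit_hierarchical(d$y, d$sa, na)
  expect_equal(fit$n_used, 10)
  expect_equal(fit$df_change, c(1, 6))
  ref <- fit_hierarchical(d$y[-c(2, 9)], d$sa[-c(2, 9)], d$na[-c(2, 9)])
  expect_equal(fit$step2$coefficients$b, ref$step2$coefficients$b, tolerance = 1e-12)
})

test_that("generating coefficients are recovered within 2 robust SEs", {
  # consistency of least squares on simulated cohorts with known truth
  cfg_args <- list(n_hsa = 1417, n_lsa = 583, na_missing_rate = 0)
  cfg <- do.call(cohort_config, c(cfg_args, seed = 1234))
  sim <- simulate_cohort(cfg, trials = FALSE)
  fit <- fit_hierarchical(sim$truth$pse, sim$truth$sa,
                          sqrt(sim$truth$panas_na))
  co <- fit$step2$coefficients
  for (j in 2:4) {
    truth_j <- c(NA, cfg$b1, cfg$b2, cfg$b3)[j]
    expect_lt(abs(co$b[j] - truth_j), 2 * co$se_robust[j])
  }
  expect_lt(fit$p_change, 0.05)   # b3 > 0 detectable at n = 2000

  # coverage sweep: per-coefficient 2-SE coverage across 300 small cohorts
  hits <- matrix(NA, 300, 3)
  for (r in 1:300) {
    s <- simulate_cohort(do.call(cohort_config,
                                 c(list(n_hsa = 90, n_lsa = 37,
                                        na_missing_rate = 0), seed = 5000 + r)),
                         trials = FALSE)
    f <- fit_hierarchical(s$truth$pse, s$truth$sa, sqrt(s$truth$panas_na))
    cc <- f$step2$coefficients
    tr <- c(cohort_config()$b1, cohort_config()$b2, cohort_config()$b3)
    hits[r, ] <- abs(cc$b[2:4] - tr) < 2 * cc$se_robust[2:4]
  }
  expect_true(all(colMeans(hits) >= 0.93))
})
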