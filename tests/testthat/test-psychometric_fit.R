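test_that("aggregate_levels tabulates valid trials per design level", {
  tt <- make_trials("a", rep(0, 8), c(rep("happy", 4), rep("angry", 4)))
  counts <- aggregate_levels(tt)
  at0 <- counts[counts$level == 0, ]
  expect_equal(at0$n_valid, 8)
  expect_equal(at0$k_happy, 4)
  expect_equal(nrow(counts), 9)            # zero-count levels retained
  expect_equal(sum(counts$n_valid), 8)

  tt2 <- make_trials("a", rep(10, 4), c("happy", "omitted", "angry", "omitted"))
  c2 <- aggregate_levels(tt2)
  expect_equal(c2$n_valid[c2$level == 10], 2)
  expect_equal(c2$k_happy[c2$level == 10], 1)

  expect_error(aggregate_levels(make_trials("a", 0, "omitted")), "no valid trials")
})

test_that("aggregation is consistent with the QC trial count", {
  tt <- simulate_observer(observer_params(mu = 2, sigma = 9, omission_rate = 0.1),
                          seed = 31, participant_id = "x")
  expect_equal(sum(aggregate_levels(tt)$n_valid), count_valid_trials(tt))
})

test_that("ML fit recovers noise-free parameters and beats a local grid oracle", {
  counts <- noise_free_counts(mu = 0, sigma = 10, n_per_level = 1000)
  fit <- fit_psychometric(counts)
  expect_true(fit$converged)
  expect_gt(fit$mu, -0.5); expect_lt(fit$mu, 0.5)
  expect_gt(fit$sigma, 9.5); expect_lt(fit$sigma, 10.5)

  # independent oracle: exhaustive 0.1-resolution grid of the same likelihood
  grid <- expand.grid(mu = seq(-5, 5, by = 0.1), sigma = seq(7, 13, by = 0.1))
  ll <- mapply(function(m, s) {
    f <- pmin(pmax(pnorm((counts$level - m) / s), 1e-9), 1 - 1e-9)
    sum(counts$k_happy * log(f) + (counts$n_valid - counts$k_happy) * log(1 - f))
  }, grid$mu, grid$sigma)
  expect_gte(fit$loglik, max(ll) - 1e-9)
  best <- grid[which.max(ll), ]
  expect_lt(abs(fit$mu - best$mu), 0.2)
  expect_lt(abs(fit$sigma - best$sigma), 0.2)
})

test_that("mirrored data negate mu and preserve sigma", {
  counts <- noise_free_counts(mu = 6, sigma = 12, n_per_level = 200)
  mirrored <- data.frame(level = rev(-counts$level),
                         n_valid = rev(counts$n_valid),
                         k_happy = rev(counts$n_valid - counts$k_happy))
  f1 <- fit_psychometric(counts)
  f2 <- fit_psychometric(mirrored)
  expect_equal(f2$mu, -f1$mu, tolerance = 1e-3)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-3)
})

test_that("fits are equivariant under shifting and scaling of the axis", {
  counts <- noise_free_counts(mu = -4, sigma = 14, n_per_level = 400)
  f0 <- fit_psychometric(counts)
  shifted <- counts; shifted$level <- counts$level + 20
  fs <- fit_psychometric(shifted)
  expect_equal(fs$mu, f0$mu + 20, tolerance = 5e-3)
  expect_equal(fs$sigma, f0$sigma, tolerance = 5e-3)
  scaled <- counts; scaled$level <- counts$level * 0.5
  fc <- fit_psychometric(scaled)
  expect_equal(fc$mu, f0$mu * 0.5, tolerance = 5e-3)
  expect_equal(fc$sigma, f0$sigma * 0.5, tolerance = 5e-3)
})

test_that("degenerate response patterns are flagged, not silently estimated", {
  all_happy <- data.frame(level = c(-40, 0, 40), n_valid = 10, k_happy = 10)
  f <- fit_psychometric(all_happy)
  expect_false(f$converged)
  expect_equal(f$mu, -100)                 # pinned at the boundary
  all_angry <- data.frame(level = c(-40, 0, 40), n_valid = 10, k_happy = 0)
  f2 <- fit_psychometric(all_angry)
  expect_false(f2$converged)
  expect_equal(f2$mu, 100)
  expect_error(fit_psychometric(data.frame(level = 0, n_valid = 8, k_happy = 4)),
               "at least 2 levels")
})

test_that("pse_of solves F(x) = 0.5, bisection cross-check", {
  fit <- list(mu = 21.95, sigma = 8, guess = 0, lapse = 0)
  expect_equal(pse_of(fit), 21.95)
  expect_equal(pse_of(list(mu = 0, sigma = 33, guess = 0.1, lapse = 0.1)), 0)

  # asymmetric asymptotes: solve by bisection on the raw curve
  fit2 <- list(mu = 0, sigma = 10, guess = 0.1, lapse = 0)
  f <- function(x) 0.1 + 0.9 * pnorm(x / 10) - 0.5
  bis <- uniroot(f, c(-50, 50), tol = 1e-12)$root
  expect_equal(pse_of(fit2), bis, tolerance = 1e-9)
  expect_equal(pse_of(fit2), 10 * qnorm(4 / 9), tolerance = 1e-12)
})

test_that("slope_at_pse matches the closed form and a finite difference", {
  expect_equal(slope_at_pse(list(mu = 0, sigma = 1, guess = 0, lapse = 0)),
               1 / sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(slope_at_pse(list(mu = 0, sigma = 1, guess = 0, lapse = 0)),
               0.39894, tolerance = 1e-5)
  expect_equal(slope_at_pse(list(mu = 3, sigma = 0.5249, guess = 0, lapse = 0)),
               0.760, tolerance = 1e-3)

  fit <- list(mu = -7, sigma = 13, guess = 0.05, lapse = 0.12)
  x0 <- pse_of(fit)
  h <- 1e-4 * fit$sigma
  fd <- (psychometric_probability(x0 + h, fit) -
           psychometric_probability(x0 - h, fit)) / (2 * h)
  expect_equal(slope_at_pse(fit), fd, tolerance = 1e-6)
})

test_that("deviance is zero at saturation and matches a hand-computed toy", {
  # F equals the empirical proportions exactly -> saturated, deviance 0
  s <- 10 / qnorm(0.75)
  counts <- data.frame(level = c(-10, 0, 10), n_valid = c(8, 8, 8),
                       k_happy = c(2, 4, 6))
  fit <- list(mu = 0, sigma = s, guess = 0, lapse = 0, counts = counts)
  expect_lt(deviance_gof(fit)$deviance, 1e-12)

  # 3-level toy, hand-computed from the deviance formula
  toy <- data.frame(level = c(-10, 0, 10), n_valid = c(10, 10, 10),
                    k_happy = c(2, 5, 9))
  fit2 <- list(mu = 0, sigma = 10, guess = 0, lapse = 0)
  f <- pnorm(c(-1, 0, 1))
  k <- toy$k_happy; n <- toy$n_valid
  dev_hand <- 2 * sum(k * log(k / (n * f)) + (n - k) * log((n - k) / (n * (1 - f))))
  got <- deviance_gof(fit2, toy)
  expect_equal(got$deviance, dev_hand, tolerance = 1e-12)
  expect_equal(sign(got$residuals$residual), sign(k / n - f))
})

test_that("deviance is non-negative across random curves and counts", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:12, 9, replace = TRUE)
    k <- rbinom(9, n, runif(9))
    counts <- data.frame(level = c(-80, -40, -20, -10, 0, 10, 20, 40, 80),
                         n_valid = n, k_happy = k)
    fit <- list(mu = runif(1, -50, 50), sigma = runif(1, 0.5, 50),
                guess = 0, lapse = 0)
    expect_gte(deviance_gof(fit, counts)$deviance, 0)
  }
})

test_that("optional shared lapse stays within its box and improves fit", {
  # 2% true lapse: the lapse-fitting variant should not do worse
  set.seed(12)
  p <- observer_params(mu = 0, sigma = 10, guess = 0, lapse = 0.03)
  tt <- simulate_observer(p, design_spec(trials_per_level = rep(50L, 9)), seed = 5)
  counts <- aggregate_levels(tt)
  f0 <- fit_psychometric(counts)
  f1 <- fit_psychometric(counts, fit_lapse = TRUE)
  expect_gte(f1$lapse, 0); expect_lte(f1$lapse, 0.05)
  expect_gte(f1$loglik, f0$loglik - 1e-8)
})

test_that("fit_cohort returns one flagged row per included participant", {
  sim <- simulate_cohort(cohort_config(n_hsa = 3, n_lsa = 2, seed = 21))
  qc <- apply_exclusions(sim$trials)
  fits <- fit_cohort(sim$trials, qc = qc)
  expect_equal(sort(fits$participant_id), sort(qc$participant_id[qc$included]))
  expect_true(all(c("pse", "slope", "deviance", "converged") %in% names(fits)))
  expect_equal(nrow(fit_cohort(sim$trials[0, ])), 0)
})
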