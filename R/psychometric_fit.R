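# Closed forms shared by the generator and the fitted objects.
# PSE solves F(x) = 0.5:  x = mu + sigma * qnorm((0.5 - gamma)/(1 - gamma - lambda));
# the slope is F'(x) evaluated there.
pse_closed_form <- function(mu, sigma, gamma = 0, lambda = 0) {
  mu + sigma * stats::qnorm((0.5 - gamma) / (1 - gamma - lambda))
}

slope_closed_form <- function(mu, sigma, gamma = 0, lambda = 0) {
  z0 <- stats::qnorm((0.5 - gamma) / (1 - gamma - lambda))
  (1 - gamma - lambda) * stats::dnorm(z0) / sigma
}

#' Aggregate one participant's trials into per-level counts
#'
#' Drops omitted trials and tabulates, for every design level, the number of
#' valid trials and the number judged happy. Levels with zero valid trials
#' are retained with `n_valid = 0`.
#'
#' @param trials Trial table rows for a single participant.
#' @param levels The design's morph levels.
#' @return A `data.frame` with columns `level`, `n_valid`, `k_happy`, sorted
#'   by level.
#' @export
aggregate_levels <- function(trials, levels = MORPH_LEVELS) {
  v <- trials[trials$response %in% c("happy", "angry"), , drop = FALSE]
  if (NROW(v) == 0) stopf("no valid trials to aggregate")
  levels <- sort(levels)
  n_valid <- vapply(levels, function(l) sum(v$morph_level == l), integer(1))
  k_happy <- vapply(levels, function(l) {
    sum(v$morph_level == l & v$response == "happy")
  }, integer(1))
  data.frame(level = levels, n_valid = n_valid, k_happy = k_happy)
}

# Negative binomial log-likelihood of (mu, sigma) given level counts, with
# the curve clipped away from 0/1 so boundary parameters stay finite.
pf_nll <- function(mu, sigma, counts, gamma, lambda) {
  f <- clip01(pf_prob(counts$level, mu, sigma, gamma, lambda))
  -sum(counts$k_happy * log(f) + (counts$n_valid - counts$k_happy) * log1p(-f))
}

#' Fit a cumulative-normal psychometric function by maximum likelihood
#'
#' Maximises the binomial log-likelihood
#' \deqn{\sum_x k_x \log F(x) + (n_x - k_x) \log(1 - F(x))}
#' with \eqn{F(x) = \gamma + (1-\gamma-\lambda)\Phi((x-\mu)/\sigma)} over
#' \eqn{(\mu, \sigma)}, with the asymptotes \eqn{(\gamma, \lambda)} fixed by
#' default (optionally a shared lapse \eqn{\lambda \in [0, 0.05]} is fitted).
#' Optimisation uses a deterministic coarse grid (21 `mu` points over the
#' observed level range, 25 log-spaced `sigma` points in [0.1, 100],
#' tie-broken to the lowest `sigma`) followed by Nelder-Mead simplex
#' refinement on \eqn{(\mu, \log\sigma)}, restarted once from its own
#' solution. `mu` is bounded to [-100, 100] and `sigma` to [0.05, 200].
#'
#' Degenerate data (all valid responses happy, or all angry) cannot identify
#' `mu`; the fit is returned flagged `converged = FALSE` with `mu` pinned at
#' the boundary rather than raising, so cohort runs complete.
#'
#' @param counts Per-level counts from [aggregate_levels()].
#' @param guess Fixed guess rate \eqn{\gamma} (default 0).
#' @param lapse Fixed lapse rate \eqn{\lambda} (default 0); ignored when
#'   `fit_lapse = TRUE`.
#' @param fit_lapse Fit a shared lapse in [0, 0.05] instead of fixing it.
#' @param mu_bounds,sigma_bounds Box constraints on the estimates.
#' @return An object of class `psychometric_fit`: `mu`, `sigma`, `guess`,
#'   `lapse`, `loglik`, `deviance`, `converged`, `n_valid_trials`, `pse`,
#'   `slope_at_pse`, and the input `counts`.
#' @export
fit_psychometric <- function(counts, guess = 0, lapse = 0, fit_lapse = FALSE,
                             mu_bounds = c(-100, 100),
                             sigma_bounds = c(0.05, 200)) {
  counts <- counts[counts$n_valid > 0, , drop = FALSE]
  if (NROW(counts) < 2) stopf("need at least 2 levels with valid trials")
  ntot <- sum(counts$n_valid)
  ktot <- sum(counts$k_happy)

  make_fit <- function(mu, sigma, gamma, lambda, loglik, converged) {
    fit <- structure(list(
      mu = mu, sigma = sigma, guess = gamma, lapse = lambda,
      loglik = loglik, deviance = NA_real_, converged = converged,
      n_valid_trials = ntot,
      pse = pse_closed_form(mu, sigma, gamma, lambda),
      slope_at_pse = slope_closed_form(mu, sigma, gamma, lambda),
      counts = counts), class = "psychometric_fit")
    fit$deviance <- deviance_gof(fit, counts)$deviance
    fit
  }

  if (ktot == 0 || ktot == ntot) {
    # all-angry pushes mu to +bound, all-happy to -bound
    mu_b <- if (ktot == 0) mu_bounds[2] else mu_bounds[1]
    lam <- if (fit_lapse) 0 else lapse
    ll <- -pf_nll(mu_b, sigma_bounds[1], counts, guess, lam)
    return(make_fit(mu_b, sigma_bounds[1], guess, lam, ll, converged = FALSE))
  }

  gamma <- guess
  lam0 <- if (fit_lapse) 0 else lapse

  # deterministic coarse initialisation
  mu_grid <- seq(min(counts$level), max(counts$level), length.out = 21)
  sigma_grid <- exp(seq(log(0.1), log(100), length.out = 25))
  grid <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  nll_grid <- mapply(pf_nll, grid$mu, grid$sigma,
                     MoreArgs = list(counts = counts, gamma = gamma, lambda = lam0))
  best <- order(nll_grid, grid$sigma)[1]

  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  obj <- function(par) {
    mu <- clamp(par[1], mu_bounds)
    sigma <- clamp(exp(par[2]), sigma_bounds)
    lambda <- if (fit_lapse) 0.05 * stats::plogis(par[3]) else lam0
    pf_nll(mu, sigma, counts, gamma, lambda)
  }
  par0 <- c(grid$mu[best], log(grid$sigma[best]))
  if (fit_lapse) par0 <- c(par0, stats::qlogis(0.2))  # lambda start 0.01
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))

  mu_hat <- clamp(opt$par[1], mu_bounds)
  sigma_hat <- clamp(exp(opt$par[2]), sigma_bounds)
  lam_hat <- if (fit_lapse) 0.05 * stats::plogis(opt$par[3]) else lam0
  tol_mu <- 1e-4 * diff(mu_bounds)
  at_bound <- mu_hat <= mu_bounds[1] + tol_mu || mu_hat >= mu_bounds[2] - tol_mu ||
    sigma_hat >= sigma_bounds[2] * (1 - 1e-4)
  make_fit(mu_hat, sigma_hat, gamma, lam_hat, -opt$value,
           converged = opt$convergence == 0 && !at_bound)
}

#' Point of subjective equality of a fitted curve
#'
#' The morph level at which the fitted curve crosses 0.5, i.e. the face
#' judged happy and angry equally often. Equals `mu` when the asymptotes are
#' symmetric (`guess == lapse`). A positive PSE is a negative perceptual
#' bias: extra physical happiness is needed for the face to look neutral.
#'
#' @param fit A `psychometric_fit` (or any list with `mu`, `sigma`, `guess`,
#'   `lapse`).
#' @return PSE in signed morph-%.
#' @export
pse_of <- function(fit) {
  pse_closed_form(fit$mu, fit$sigma, fit$guess %||% 0, fit$lapse %||% 0)
}

#' Slope of the fitted psychometric function at its PSE
#'
#' The derivative of the fitted curve at the 50% point, in probability per
#' morph-%. For symmetric asymptotes this is
#' \eqn{(1-\gamma-\lambda)/(\sigma\sqrt{2\pi})}. Steeper slopes indicate a
#' more categorical happy/angry boundary.
#'
#' @inheritParams pse_of
#' @return Slope in probability per morph-%.
#' @export
slope_at_pse <- function(fit) {
  slope_closed_form(fit$mu, fit$sigma, fit$guess %||% 0, fit$lapse %||% 0)
}

#' Binomial deviance goodness of fit
#'
#' Deviance of the fitted curve against the saturated model,
#' \deqn{D = 2\sum_x [k \log(k/(nF)) + (n-k)\log((n-k)/(n(1-F)))],}
#' with the convention \eqn{0 \log 0 = 0}, plus signed per-level residuals
#' (sign of the empirical-minus-fitted proportion, magnitude the square root
#' of that level's deviance contribution).
#'
#' @param fit A `psychometric_fit`.
#' @param counts Per-level counts (defaults to those stored in the fit).
#' @return List with `deviance` and a `residuals` data.frame.
#' @export
deviance_gof <- function(fit, counts = fit$counts) {
  counts <- counts[counts$n_valid > 0, , drop = FALSE]
  f <- clip01(pf_prob(counts$level, fit$mu, fit$sigma,
                      fit$guess %||% 0, fit$lapse %||% 0))
  k <- counts$k_happy
  n <- counts$n_valid
  xlogx <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  dev_i <- 2 * (xlogx(k, n * f) + xlogx(n - k, n * (1 - f)))
  dev_i <- pmax(dev_i, 0)  # guard tiny negative rounding
  list(deviance = sum(dev_i),
       residuals = data.frame(level = counts$level,
                              residual = sign(k / n - f) * sqrt(dev_i)))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit (cumulative normal, ML): mu = %.3f, sigma = %.3f\n",
    x$mu, x$sigma))
  cat(sprintf("  PSE = %.3f morph-%%, slope at PSE = %.4f per morph-%%\n",
              x$pse, x$slope_at_pse))
  cat(sprintf("  loglik = %.3f, deviance = %.3f, n = %d, converged: %s\n",
              x$loglik, x$deviance, x$n_valid_trials, x$converged))
  invisible(x)
}

#' Fit every included participant in a trial table
#'
#' Applies [aggregate_levels()] + [fit_psychometric()] per participant and
#' returns a flat fits table. Participants excluded by the QC ledger are
#' skipped; non-converged fits are returned flagged for the caller to drop
#' and ledger.
#'
#' @param trials A validated trial table.
#' @param qc Optional ledger from [apply_exclusions()]; only `included`
#'   participants are fitted.
#' @param ... Passed to [fit_psychometric()].
#' @return A `data.frame` with one row per fitted participant.
#' @export
fit_cohort <- function(trials, qc = NULL, ...) {
  ids <- unique(trials$participant_id)
  if (!is.null(qc)) ids <- intersect(ids, qc$participant_id[qc$included])
  rows <- lapply(ids, function(id) {
    tt <- trials[trials$participant_id == id, , drop = FALSE]
    fit <- fit_psychometric(aggregate_levels(tt), ...)
    data.frame(participant_id = id, mu = fit$mu, sigma = fit$sigma,
               guess = fit$guess, lapse = fit$lapse, pse = fit$pse,
               slope = fit$slope_at_pse, loglik = fit$loglik,
               deviance = fit$deviance, n_valid_trials = fit$n_valid_trials,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    data.frame(participant_id = character(0), mu = numeric(0), sigma = numeric(0),
               guess = numeric(0), lapse = numeric(0), pse = numeric(0),
               slope = numeric(0), loglik = numeric(0), deviance = numeric(0),
               n_valid_trials = integer(0), converged = logical(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}
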