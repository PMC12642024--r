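#' Observer model parameters
#'
#' Parameters of a guess/lapse-augmented cumulative-normal 2AFC observer:
#' the probability of a "happy" judgment at signed morph level `x` is
#' \deqn{F(x) = \gamma + (1 - \gamma - \lambda)\,\Phi((x - \mu)/\sigma),}
#' where \eqn{\mu} is the point of subjective equality (PSE) in morph-%,
#' \eqn{\sigma > 0} the psychometric width, \eqn{\gamma} the lower-asymptote
#' guess rate and \eqn{\lambda} the upper-asymptote lapse rate. Each trial is
#' independently left unanswered with probability `omission_rate`, emulating
#' responses falling outside the fixed response window.
#'
#' @param mu PSE, signed morph-%.
#' @param sigma Width, morph-% (> 0).
#' @param guess Guess rate \eqn{\gamma \in [0, 0.5)}.
#' @param lapse Lapse rate \eqn{\lambda \in [0, 0.5)}.
#' @param omission_rate Per-trial probability of no response, in [0, 1).
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(mu = 0, sigma = 12, guess = 0, lapse = 0,
                            omission_rate = 0) {
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be > 0 (got %s)", sigma)
  if (guess < 0 || guess >= 0.5) stopf("guess must be in [0, 0.5)")
  if (lapse < 0 || lapse >= 0.5) stopf("lapse must be in [0, 0.5)")
  if (guess + lapse >= 1) stopf("guess + lapse must be < 1")
  if (omission_rate < 0 || omission_rate >= 1) stopf("omission_rate must be in [0, 1)")
  structure(list(mu = mu, sigma = sigma, guess = guess, lapse = lapse,
                 omission_rate = omission_rate),
            class = "observer_params")
}

#' Trial design: morph levels and repetitions
#'
#' The default reproduces the 64-trial design: 8 trials at each of the
#' \eqn{\pm 40}, \eqn{\pm 20}, \eqn{\pm 10} and neutral (0) morphs, and 4 at
#' each \eqn{\pm 80} morph.
#'
#' @param levels Ordered signed morph-% levels.
#' @param trials_per_level Positive integer repetition count per level.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(levels = MORPH_LEVELS,
                        trials_per_level = c(4, 8, 8, 8, 8, 8, 8, 8, 4)) {
  if (length(levels) != length(trials_per_level)) {
    stopf("levels and trials_per_level must have equal length")
  }
  if (any(trials_per_level < 1) || any(trials_per_level != round(trials_per_level))) {
    stopf("trials_per_level must be positive integers")
  }
  if (is.unsorted(levels, strictly = TRUE)) stopf("levels must be strictly increasing")
  structure(list(levels = as.numeric(levels),
                 trials_per_level = as.integer(trials_per_level)),
            class = "design_spec")
}

# Raw psychometric curve; vectorised over x.
pf_prob <- function(x, mu, sigma, gamma = 0, lambda = 0) {
  gamma + (1 - gamma - lambda) * stats::pnorm((x - mu) / sigma)
}

#' Psychometric probability of a "happy" judgment
#'
#' @param x Signed morph level(s), morph-%.
#' @param params An [observer_params()] object (or any list with fields
#'   `mu`, `sigma`, `guess`, `lapse`).
#' @return Probability of a "happy" judgment at each `x`; strictly increasing
#'   in `x` and bounded in `(guess, 1 - lapse)`.
#' @export
psychometric_probability <- function(x, params) {
  if (is.null(params$sigma) || !is.finite(params$sigma) || params$sigma <= 0) {
    stopf("sigma must be > 0")
  }
  pf_prob(x, params$mu, params$sigma, params$guess %||% 0, params$lapse %||% 0)
}

#' Simulate one observer's trial table
#'
#' Draws one Bernoulli "happy"/"angry" judgment per scheduled trial at the
#' observer's psychometric probability, then independently marks each trial
#' omitted with probability `omission_rate`. Presentation order is randomised.
#' Identical `seed` and inputs give byte-identical output.
#'
#' @param params An [observer_params()] object.
#' @param design A [design_spec()] object.
#' @param seed Integer RNG seed.
#' @param participant_id Id string stamped on every record.
#' @return A validated trial table (`data.frame`) with
#'   `sum(design$trials_per_level)` rows.
#' @export
simulate_observer <- function(params, design = design_spec(), seed = 1L,
                              participant_id = "obs001") {
  levels <- rep(design$levels, design$trials_per_level)
  n <- length(levels)
  with_seed(seed, {
    ord <- sample.int(n)
    levels <- levels[ord]
    p <- psychometric_probability(levels, params)
    happy <- stats::runif(n) < p
    omitted <- stats::runif(n) < params$omission_rate
  })
  response <- ifelse(omitted, "omitted", ifelse(happy, "happy", "angry"))
  validate_trials(data.frame(
    participant_id = participant_id,
    trial_index = seq_len(n),
    morph_level = levels,
    face_id = NA_character_,
    response = response,
    stringsAsFactors = FALSE
  ))
}

#' Cohort generating configuration
#'
#' Describes a synthetic cohort with a known group-by-negative-affect
#' structure. Negative state affect (PANAS-NA) is drawn per group from a
#' normal distribution, rounded to integers and clamped to the scale range
#' [10, 50]. Each participant's true PSE is
#' \deqn{PSE = b_0 + b_1 SA + b_2 z + b_3 SA\,z + \varepsilon,}
#' with `SA` coded 0 = LSA, 1 = HSA, `z` the square-root-transformed NA
#' centered at the realised cohort mean (the scale on which the moderation
#' model is fitted downstream), and \eqn{\varepsilon \sim N(0,
#' pse\_residual\_sd^2)}. Psychometric widths are drawn log-normally.
#'
#' Defaults target the observed cohort texture: group sizes 90 HSA / 37 LSA,
#' NA means/SDs near 13.81 (3.38) and 11.68 (2.02), ~7% omitted trials, and
#' a social-anxiety effect on PSE that is present mainly at high NA.
#'
#' @param n_hsa,n_lsa Group sizes (each >= 2).
#' @param na_mean_hsa,na_sd_hsa,na_mean_lsa,na_sd_lsa Raw PANAS-NA moments.
#' @param b0,b1,b2,b3 Generating coefficients: intercept, SA main effect,
#'   centered sqrt-NA main effect, SA x sqrt-NA interaction (morph-% units).
#' @param pse_residual_sd Residual SD of true PSE, morph-% (>= 0).
#' @param sigma_meanlog,sigma_sdlog Log-normal location/scale for widths.
#' @param guess,lapse,omission_rate Observer nuisance parameters.
#' @param na_missing_rate Probability a participant's PANAS records are
#'   missing (the latent NA still drives their PSE).
#' @param seed Master integer seed; per-participant substreams are derived
#'   from it so cohort size changes do not reshuffle earlier participants.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hsa = 90, n_lsa = 37,
                          na_mean_hsa = 13.81, na_sd_hsa = 3.38,
                          na_mean_lsa = 11.68, na_sd_lsa = 2.02,
                          b0 = 3.0, b1 = 6.5, b2 = -10, b3 = 15.7,
                          pse_residual_sd = 11.5,
                          sigma_meanlog = log(12), sigma_sdlog = 0.35,
                          guess = 0, lapse = 0, omission_rate = 0.07,
                          na_missing_rate = 0.04, seed = 1L) {
  if (n_hsa < 2 || n_lsa < 2) stopf("each group needs at least 2 participants")
  if (na_sd_hsa <= 0 || na_sd_lsa <= 0) stopf("na_sd must be > 0")
  if (pse_residual_sd < 0) stopf("pse_residual_sd must be >= 0")
  structure(list(n_hsa = n_hsa, n_lsa = n_lsa,
                 na_mean_hsa = na_mean_hsa, na_sd_hsa = na_sd_hsa,
                 na_mean_lsa = na_mean_lsa, na_sd_lsa = na_sd_lsa,
                 b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                 pse_residual_sd = pse_residual_sd,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 guess = guess, lapse = lapse, omission_rate = omission_rate,
                 na_missing_rate = na_missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a full synthetic cohort
#'
#' Generates participants (metadata), their ground-truth psychometric
#' parameters, and (optionally) their trial tables under the default 64-trial
#' design. The ground-truth table lets every downstream stage be checked
#' against known generating values.
#'
#' @param config A [cohort_config()] object.
#' @param design A [design_spec()] object.
#' @param trials If `FALSE`, skip trial simulation and return only the
#'   participant and ground-truth tables (fast path for calibration studies
#'   that operate on true PSEs directly).
#' @return A list with elements `trials` (validated trial table, or `NULL`),
#'   `participants` (validated participant table) and `truth` (per-participant
#'   generating values: sa, latent NA, true mu/sigma/pse/slope).
#' @export
simulate_cohort <- function(config = cohort_config(), design = design_spec(),
                            trials = TRUE) {
  n <- config$n_hsa + config$n_lsa
  sa <- c(rep(1L, config$n_hsa), rep(0L, config$n_lsa))
  ids <- sprintf("P%03d", seq_len(n))

  # One RNG substream per participant, keyed by (master seed, index): growing
  # the cohort never changes the draws of already-existing participants.
  sub_seeds <- vapply(seq_len(n), function(i) derive_seed(config$seed, i),
                      integer(1))
  one <- function(i) {
    hsa <- sa[i] == 1L
    with_seed(sub_seeds[i], {
      c(na_raw = pmin(pmax(round(stats::rnorm(
          1, if (hsa) config$na_mean_hsa else config$na_mean_lsa,
          if (hsa) config$na_sd_hsa else config$na_sd_lsa)), 10), 50),
        sigma = stats::rlnorm(1, config$sigma_meanlog, config$sigma_sdlog),
        eps = stats::rnorm(1, 0, config$pse_residual_sd),
        na_missing = as.numeric(stats::runif(1) < config$na_missing_rate),
        # cosmetic questionnaire scores consistent with the inclusion rules
        bfne = if (hsa) pmin(pmax(round(stats::rnorm(1, 32.1, 4.4)), 25), 40)
               else pmin(pmax(round(stats::rnorm(1, 10.1, 1.6)), 8), 12),
        dass = pmin(pmax(round(stats::rnorm(1, if (hsa) 8.6 else 5.4, 4.7)), 0), 17),
        pa = pmin(pmax(round(stats::rnorm(1, if (hsa) 27.3 else 32.7, 8.2)), 10), 50))
    })
  }
  m <- vapply(seq_len(n), one, numeric(7))
  draw <- list(na_raw = m["na_raw", ], sigma = m["sigma", ], eps = m["eps", ],
               na_missing = m["na_missing", ] > 0, bfne = m["bfne", ],
               dass = m["dass", ], pa = m["pa", ])

  z <- sqrt(draw$na_raw) - mean(sqrt(draw$na_raw))
  mu_true <- config$b0 + config$b1 * sa + config$b2 * z +
    config$b3 * sa * z + draw$eps

  truth <- data.frame(
    participant_id = ids, sa = sa, panas_na = draw$na_raw,
    na_sqrt_centered = z, mu = mu_true, sigma = draw$sigma,
    guess = config$guess, lapse = config$lapse,
    pse = pse_closed_form(mu_true, draw$sigma, config$guess, config$lapse),
    slope = slope_closed_form(mu_true, draw$sigma, config$guess, config$lapse),
    stringsAsFactors = FALSE
  )
  participants <- validate_participants(data.frame(
    participant_id = ids,
    sa_status = ifelse(sa == 1L, "HSA", "LSA"),
    bfne_s = draw$bfne,
    dass_depression = draw$dass,
    panas_pa = ifelse(draw$na_missing, NA, draw$pa),
    panas_na = ifelse(draw$na_missing, NA, draw$na_raw),
    age = NA_real_, gender = NA_character_,
    stringsAsFactors = FALSE
  ))

  trial_tab <- NULL
  if (trials) {
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      p <- observer_params(mu = mu_true[i], sigma = draw$sigma[i],
                           guess = config$guess, lapse = config$lapse,
                           omission_rate = config$omission_rate)
      parts[[i]] <- simulate_observer(p, design,
                                      seed = derive_seed(sub_seeds[i], 1L),
                                      participant_id = ids[i])
    }
    trial_tab <- do.call(rbind, parts)
    rownames(trial_tab) <- NULL
  }
  list(trials = trial_tab, participants = participants, truth = truth)
}
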