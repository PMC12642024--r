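#' Build a run configuration
#'
#' Exactly one of `trials_path` (with `participants_path`) or `simulate`
#' must be supplied: a run either reads real delimited-text inputs or
#' generates a synthetic cohort.
#'
#' @param trials_path,participants_path CSV inputs for a real-data run.
#' @param simulate A named list of [cohort_config()] arguments for a
#'   synthetic run (an empty list uses the defaults).
#' @param qc Named list of [apply_exclusions()] thresholds.
#' @param fit Named list of [fit_psychometric()] options.
#' @param alpha Significance / gate level.
#' @param hc_type Robust covariance flavor for the moderation models.
#' @param seed Master seed (recorded in the report; drives simulation).
#' @param out Optional output directory for [write_report()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(trials_path = NULL, participants_path = NULL,
                       simulate = NULL, qc = list(), fit = list(),
                       alpha = 0.05, hc_type = "HC3", seed = 1L, out = NULL) {
  real <- !is.null(trials_path)
  if (real == !is.null(simulate)) {
    stopf("exactly one of trials_path or simulate must be given")
  }
  if (real && is.null(participants_path)) {
    stopf("participants_path is required with trials_path")
  }
  structure(list(trials_path = trials_path,
                 participants_path = participants_path,
                 simulate = simulate, qc = qc, fit = fit, alpha = alpha,
                 hc_type = hc_type, seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> QC -> per-participant psychometric fits ->
#' group inference -> moderation, and assembles a structured report.
#' Participants failing QC or fit convergence are excluded downstream and
#' appear in the exclusion ledger; every input participant appears exactly
#' once in fits or in that ledger. Identical config + seed give an identical
#' report.
#'
#' @param config A [run_config()].
#' @return The analysis report (list); also written to `config$out` when set.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("[stage %s] %s", name, conditionMessage(e))
    })
  }
  notes <- character(0)

  dat <- stage("input", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(cohort_config, c(config$simulate,
                                      list(seed = config$seed)))
      simulate_cohort(cfg)
    } else {
      list(trials = read_trials(config$trials_path),
           participants = read_participants(config$participants_path),
           truth = NULL)
    }
  })

  qc <- stage("qc", do.call(apply_exclusions, c(list(dat$trials), config$qc)))
  fits <- stage("fit", do.call(fit_cohort,
                               c(list(dat$trials, qc = qc), config$fit)))

  bad_fit <- fits$participant_id[!fits$converged]
  exclusions <- qc[!qc$included, c("participant_id", "reasons")]
  if (length(bad_fit) > 0) {
    exclusions <- rbind(exclusions,
                        data.frame(participant_id = bad_fit,
                                   reasons = "fit_not_converged"))
    fits <- fits[fits$converged, , drop = FALSE]
  }
  rownames(exclusions) <- rownames(fits) <- NULL

  # analysis table: fits joined to metadata, NA square-root transformed
  ana <- merge(fits, dat$participants, by = "participant_id", sort = TRUE)
  ana$sa <- ifelse(ana$sa_status == "HSA", 1L, 0L)
  ana$na_sqrt <- sqrt_transform(ana$panas_na)

  group_tests <- NULL
  screens <- NULL
  mod_pse <- mod_slope <- ss_pse <- NULL
  hsa <- ana[ana$sa == 1L, , drop = FALSE]
  lsa <- ana[ana$sa == 0L, , drop = FALSE]
  if (nrow(hsa) >= 2 && nrow(lsa) >= 2) {
    stage("group_inference", {
      screens <- list(pse = skew_kurtosis_check(ana$pse),
                      slope = skew_kurtosis_check(ana$slope))
      row_for <- function(measure, a, b) {
        r <- compare_groups(a, b, alpha = config$alpha)
        data.frame(measure = measure,
                   n_lsa = length(a), mean_lsa = mean(a), sd_lsa = stats::sd(a),
                   n_hsa = length(b), mean_hsa = mean(b), sd_hsa = stats::sd(b),
                   variant = r$variant, t = r$t, df = r$df, p = r$p,
                   cohens_d = r$cohens_d, levene_W = r$levene_W,
                   levene_p = r$levene_p, stringsAsFactors = FALSE)
      }
      group_tests <- rbind(row_for("pse", lsa$pse, hsa$pse),
                           row_for("slope", lsa$slope, hsa$slope))
    })
  } else {
    notes <- c(notes, "group inference skipped: fewer than 2 fitted participants in a group")
  }

  n_complete <- sum(stats::complete.cases(ana$pse, ana$sa, ana$na_sqrt))
  if (n_complete >= 8 && nrow(hsa) >= 2 && nrow(lsa) >= 2) {
    stage("moderation", {
      mod_pse <- fit_hierarchical(ana$pse, ana$sa, ana$na_sqrt,
                                  hc_type = config$hc_type)
      mod_slope <- fit_hierarchical(ana$slope, ana$sa, ana$na_sqrt,
                                    hc_type = config$hc_type)
      ss_pse <- simple_slopes(mod_pse)
    })
  } else {
    notes <- c(notes, "moderation skipped: insufficient complete cases")
  }

  report <- list(
    # `out` is excluded from the config echo: it does not affect the analysis
    # and would break byte-identity of reports written to different places
    provenance = list(package = "emobias",
                      version = as.character(utils::packageVersion("emobias")),
                      seed = config$seed,
                      config = unclass(config)[setdiff(names(config), "out")]),
    n_participants_in = length(unique(dat$trials$participant_id)),
    n_fitted = nrow(fits),
    qc_ledger = qc,
    exclusions = exclusions,
    fits = fits,
    normality_screens = screens,
    group_tests = group_tests,
    moderation_pse = if (is.null(mod_pse)) NULL else unclass_moderation(mod_pse),
    moderation_slope = if (is.null(mod_slope)) NULL else unclass_moderation(mod_slope),
    simple_slopes_pse = ss_pse,
    truth = dat$truth,
    notes = notes
  )
  if (!is.null(config$out)) write_report(report, config$out)
  invisible(report)
}

# moderation_result -> plain serialisable list (drop matrix internals)
unclass_moderation <- function(m) {
  list(step1 = m$step1, step2 = m$step2, delta_r2 = m$delta_r2,
       f_change = m$f_change, df_change = m$df_change, p_change = m$p_change,
       n_used = m$n_used, sd_na = m$sd_na, hc_type = m$hc_type)
}
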