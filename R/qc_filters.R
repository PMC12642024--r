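#' Count valid (answered) trials for one participant
#'
#' A trial is valid when it carries a `happy` or `angry` judgment; omitted
#' trials do not count.
#'
#' @param trials Trial table rows for a single participant.
#' @return Integer count (0 for empty input).
#' @export
count_valid_trials <- function(trials) {
  if (NROW(trials) == 0) return(0L)
  if (length(unique(trials$participant_id)) > 1) {
    stopf("count_valid_trials expects trials from a single participant")
  }
  sum(trials$response %in% c("happy", "angry"))
}

#' Happy proportions at the extreme morph levels
#'
#' Computes the proportion of "happy" judgments among valid trials at the
#' +80 and -80 morph levels, the attention/consistency check used for
#' inclusion. A level with no valid trials yields `NA` (undefined), which is
#' a value, not an error.
#'
#' @param trials Trial table rows for a single participant.
#' @return Named numeric vector `c(p_happy_plus80, p_happy_minus80)`.
#' @export
extreme_level_consistency <- function(trials) {
  prop_at <- function(level) {
    v <- trials[trials$morph_level == level &
                  trials$response %in% c("happy", "angry"), , drop = FALSE]
    if (NROW(v) == 0) NA_real_ else mean(v$response == "happy")
  }
  c(p_happy_plus80 = prop_at(80), p_happy_minus80 = prop_at(-80))
}

#' Apply participant-level inclusion rules
#'
#' Implements the study-style exclusion rules on a trial table and returns a
#' complete, auditable ledger covering every participant. A participant is
#' excluded iff they completed fewer than `min_trials` valid trials
#' (`too_few_trials`), judged the 80% happy morph happy less than
#' `happy_floor` of the time or the 80% angry morph happy more than
#' `angry_ceiling` of the time (`biased_extreme_responses`), or had no valid
#' trials at an extreme level so the check is unverifiable
#' (`no_extreme_trials`). Boundaries are strict: exactly `min_trials` valid
#' trials, exactly `happy_floor` at +80 and exactly `angry_ceiling` at -80
#' are all included.
#'
#' @param trials A validated trial table (any number of participants).
#' @param min_trials Minimum valid-trial count (default 30).
#' @param happy_floor Minimum happy proportion at +80 (default 0.75).
#' @param angry_ceiling Maximum happy proportion at -80 (default 0.25).
#' @return A `data.frame` ledger with one row per participant: counts,
#'   extreme proportions, `included`, and a semicolon-joined `reasons` field
#'   (empty iff included).
#' @export
apply_exclusions <- function(trials, min_trials = 30, happy_floor = 0.75,
                             angry_ceiling = 0.25) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tt <- trials[trials$participant_id == id, , drop = FALSE]
    nv <- count_valid_trials(tt)
    ex <- extreme_level_consistency(tt)
    reasons <- character(0)
    if (nv < min_trials) reasons <- c(reasons, "too_few_trials")
    if (anyNA(ex)) reasons <- c(reasons, "no_extreme_trials")
    if ((!is.na(ex[1]) && ex[1] < happy_floor) ||
        (!is.na(ex[2]) && ex[2] > angry_ceiling)) {
      reasons <- c(reasons, "biased_extreme_responses")
    }
    data.frame(participant_id = id, n_valid_trials = nv,
               p_happy_plus80 = unname(ex[1]), p_happy_minus80 = unname(ex[2]),
               included = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  ledger <- do.call(rbind, rows)
  rownames(ledger) <- NULL
  ledger
}
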