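#' Read a trial-level judgment table
#'
#' Reads a comma-separated table of single-trial emotion judgments and
#' validates it against the pipeline's schema. Required columns are
#' `participant_id`, `trial_index`, `morph_level` and `response`; `face_id`
#' is optional. `morph_level` is the signed morph percentage (happy positive)
#' and must come from the 9-level design set \{-80, -40, -20, -10, 0, 10, 20,
#' 40, 80\}; `response` is one of `happy`, `angry`, `omitted`. Omitted trials
#' are preserved, not dropped.
#'
#' @param path Path to a CSV file with a header row.
#' @param sep Field delimiter (default comma).
#' @return A validated `data.frame` of trial records.
#' @export
read_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stopf("trial file does not exist: %s", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = "character")
  validate_trials(df)
}

#' Validate a trial table against the schema
#'
#' @param df A data.frame of trial records (see [read_trials()]).
#' @return The validated data.frame with typed columns.
#' @export
validate_trials <- function(df) {
  required <- c("participant_id", "trial_index", "morph_level", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stopf("trial table schema error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!"face_id" %in% names(df)) df$face_id <- NA_character_
  df <- df[, c("participant_id", "trial_index", "morph_level", "face_id", "response")]
  df$participant_id <- as.character(df$participant_id)
  df$face_id <- as.character(df$face_id)
  df$response <- as.character(df$response)

  ti <- suppressWarnings(as.integer(df$trial_index))
  bad <- which(is.na(ti) | ti < 1L)
  if (length(bad) > 0) stopf("invalid trial_index at row(s) %s", paste(bad, collapse = ", "))
  df$trial_index <- ti

  ml <- suppressWarnings(as.numeric(df$morph_level))
  bad <- which(is.na(ml) | !(ml %in% MORPH_LEVELS))
  if (length(bad) > 0) {
    stopf("morph_level outside the design set {%s} at row(s) %s",
          paste(MORPH_LEVELS, collapse = ", "), paste(bad, collapse = ", "))
  }
  df$morph_level <- ml

  bad <- which(is.na(df$response) | !(df$response %in% RESPONSES))
  if (length(bad) > 0) {
    stopf("response outside {%s} at row(s) %s",
          paste(RESPONSES, collapse = ", "), paste(bad, collapse = ", "))
  }
  key <- paste(df$participant_id, df$trial_index, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate (participant_id, trial_index) at row(s) %s",
          paste(which(duplicated(key)), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: missing values are written as empty fields so
#' that a write/read round-trip is the identity.
#'
#' @param trials A validated trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a participant metadata table
#'
#' Reads the participant-level table (group label and questionnaire scores)
#' and validates it. `sa_status` must be consistent with the BFNE-S
#' straightforward-item cutoffs used to form the groups (HSA requires
#' `bfne_s >= 25`, LSA requires `bfne_s <= 12`; scores of 13--24 fall in the
#' excluded middle band and are rejected regardless of label). Included
#' participants must have `dass_depression <= 17`. PANAS state-affect scores
#' may be missing (empty fields) and are returned as `NA`.
#'
#' @param path Path to a CSV file with columns `participant_id`, `sa_status`,
#'   `bfne_s`, `dass_depression`, `panas_pa`, `panas_na` and optionally
#'   `age`, `gender`.
#' @return A validated `data.frame` of participant records.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stopf("participant file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  validate_participants(df)
}

#' Validate a participant table
#'
#' @param df A data.frame of participant records (see [read_participants()]).
#' @return The validated data.frame with typed columns.
#' @export
validate_participants <- function(df) {
  required <- c("participant_id", "sa_status", "bfne_s", "dass_depression",
                "panas_pa", "panas_na")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stopf("participant table schema error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!"age" %in% names(df)) df$age <- NA_character_
  if (!"gender" %in% names(df)) df$gender <- NA_character_
  df <- df[, c("participant_id", "sa_status", "bfne_s", "dass_depression",
               "panas_pa", "panas_na", "age", "gender")]
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id)) {
    stopf("duplicate participant_id: %s",
          paste(unique(df$participant_id[duplicated(df$participant_id)]), collapse = ", "))
  }
  bad <- which(!(df$sa_status %in% c("HSA", "LSA")))
  if (length(bad) > 0) stopf("sa_status must be HSA or LSA at row(s) %s", paste(bad, collapse = ", "))

  int_col <- function(col, lo, hi, allow_na = FALSE) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which((!is.na(raw) & is.na(v)) |            # unparseable
                   (is.na(v) & !allow_na) |            # missing where required
                   (!is.na(v) & (v < lo | v > hi)))    # out of range
    if (length(bad) > 0) {
      stopf("%s missing or out of range [%d, %d] at row(s) %s", col, lo, hi,
            paste(bad, collapse = ", "))
    }
    v
  }
  df$bfne_s <- int_col("bfne_s", 8L, 40L)
  df$dass_depression <- int_col("dass_depression", 0L, 21L)
  df$panas_pa <- int_col("panas_pa", 10L, 50L, allow_na = TRUE)
  df$panas_na <- int_col("panas_na", 10L, 50L, allow_na = TRUE)
  df$age <- suppressWarnings(as.numeric(df$age))

  mid <- which(df$bfne_s > 12 & df$bfne_s < 25)
  if (length(mid) > 0) {
    stopf("bfne_s in the excluded middle band (13-24) at row(s) %s",
          paste(mid, collapse = ", "))
  }
  bad <- which((df$sa_status == "HSA" & df$bfne_s < 25) |
                 (df$sa_status == "LSA" & df$bfne_s > 12))
  if (length(bad) > 0) {
    stopf("sa_status inconsistent with bfne_s cutoffs (HSA >= 25, LSA <= 12) at row(s) %s",
          paste(bad, collapse = ", "))
  }
  bad <- which(df$dass_depression > 17)
  if (length(bad) > 0) {
    stopf("dass_depression above inclusion cutoff (17) at row(s) %s",
          paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a participant table to CSV
#' @param participants A validated participant table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a full analysis report to a directory
#'
#' Serialises an analysis report (as produced by [run_pipeline()]) into one
#' machine-readable JSON document plus flat CSV side-tables (fits, QC ledger,
#' group tests, moderation tables, simple slopes). The JSON document is
#' byte-deterministic for a given report; wall-clock metadata lives only in
#' the manifest.
#'
#' @param report An analysis report list.
#' @param dir Output directory (created if absent).
#' @return Character vector of files written (the manifest), invisibly.
#' @export
write_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stopf("cannot create output directory: %s", dir)
  files <- character(0)
  put_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, na = "null",
                         null = "null", pretty = TRUE)
    files <<- c(files, name)
  }
  put_csv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE, na = "")
    files <<- c(files, name)
  }
  put_json(report, "report.json")
  empty_or <- function(x, template) if (is.null(x) || NROW(x) == 0) template else x
  put_csv(empty_or(report$fits, data.frame(participant_id = character(0))), "fits.csv")
  put_csv(empty_or(report$qc_ledger, data.frame(participant_id = character(0))), "qc_ledger.csv")
  put_csv(empty_or(report$group_tests, data.frame(measure = character(0))), "group_tests.csv")
  if (!is.null(report$moderation_pse)) {
    put_csv(moderation_table(report$moderation_pse), "moderation_pse.csv")
  }
  if (!is.null(report$moderation_slope)) {
    put_csv(moderation_table(report$moderation_slope), "moderation_slope.csv")
  }
  if (!is.null(report$simple_slopes_pse)) {
    put_csv(report$simple_slopes_pse, "simple_slopes_pse.csv")
  }
  manifest <- list(files = files, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, "manifest.json"))
}

#' Read back a serialised analysis report
#' @param path Path to a `report.json` written by [write_report()].
#' @return The report as a list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stopf("report file does not exist: %s", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
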