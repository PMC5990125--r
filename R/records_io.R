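# Readers and writers for the three deposited table layouts (true outcomes,
# student questionnaires, machine scores) and their CSV equivalents. CSV with
# the deposited column names is the canonical interchange format; XLSX is
# supported read-only where readxl is available.

read_table_any <- function(path, dialect, col_names = TRUE) {
  if (!file.exists(path)) stop_schema("File {.path {path}} does not exist.")
  dialect <- match.arg(dialect, c("auto", "csv", "xlsx"))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  if (dialect == "xlsx") {
    rlang::check_installed("readxl", reason = "to read xlsx dialects")
    out <- readxl::read_excel(path, col_names = col_names)
  } else {
    out <- readr::read_csv(path, col_names = col_names, show_col_types = FALSE,
                           progress = FALSE)
  }
  if (nrow(out) == 0 && ncol(out) == 0) stop_schema("File {.path {path}} is empty.")
  out
}

find_record_col <- function(df) {
  hit <- grep("record|report|^id$|index", names(df), ignore.case = TRUE, value = TRUE)
  if (length(hit) > 0) return(hit[[1]])
  names(df)[[1]]  # deposited files index records in the first column
}

#' Read per-record true outcome labels
#'
#' Reads a table in the deposited true-outcome layout: one row per clinical
#' record with binary columns `T_180`, `T_360`, `T_720` (0 = still
#' relapsing-remitting at that horizon, 1 = transitioned to secondary
#' progressive). Because the SP phase is absorbing, labels must be
#' non-decreasing across horizons within a record; violations are reported
#' per `monotonicity`.
#'
#' @param path Path to a CSV (or XLSX) file with a record-index column plus
#'   `T_180`, `T_360`, `T_720` label columns.
#' @param dialect `"auto"` (by extension), `"csv"`, or `"xlsx"`.
#' @param monotonicity `"warn"` (default) or `"error"` on records whose labels
#'   decrease with horizon.
#' @param quiet Suppress the row-count message.
#' @return A tibble with columns `record_id`, `T_180`, `T_360`, `T_720`.
#' @export
read_outcomes <- function(path, dialect = c("auto", "csv", "xlsx"),
                          monotonicity = c("warn", "error"), quiet = FALSE) {
  df <- read_table_any(path, match.arg(dialect))
  monotonicity <- match.arg(monotonicity)
  lab <- horizon_label_cols()
  missing <- setdiff(lab, names(df))
  if (length(missing) > 0) {
    stop_schema("Outcome file {.path {path}} lacks {length(missing)} column{?s}: {.val {missing}}.")
  }
  out <- tibble::tibble(
    record_id = df[[find_record_col(df)]],
    T_180 = as.numeric(df$T_180),
    T_360 = as.numeric(df$T_360),
    T_720 = as.numeric(df$T_720)
  )
  validate_outcomes(out, monotonicity = monotonicity)
  if (!quiet) cli::cli_inform("Read {nrow(out)} outcome record{?s} from {.path {path}}.")
  out
}

#' Validate an outcome-label table
#'
#' Checks that labels are binary, record ids unique, and labels monotone
#' non-decreasing across horizons (SP is absorbing).
#'
#' @param outcomes Tibble with `record_id`, `T_180`, `T_360`, `T_720`.
#' @inheritParams read_outcomes
#' @return `outcomes`, invisibly.
#' @export
validate_outcomes <- function(outcomes, monotonicity = c("warn", "error")) {
  monotonicity <- match.arg(monotonicity)
  lab <- horizon_label_cols()
  vals <- as.matrix(outcomes[lab])
  bad <- which(!(vals %in% c(0, 1)) | is.na(vals), arr.ind = TRUE)
  if (length(bad) > 0) {
    ids <- unique(outcomes$record_id[bad[, 1]])
    stop_validation("Non-binary outcome labels for {length(ids)} record{?s}: {.val {ids}}.")
  }
  if (anyDuplicated(outcomes$record_id)) {
    dup <- unique(outcomes$record_id[duplicated(outcomes$record_id)])
    stop_validation("{length(dup)} duplicated record id{?s}: {.val {dup}}.")
  }
  non_mono <- outcomes$record_id[vals[, 1] > vals[, 2] | vals[, 2] > vals[, 3]]
  if (length(non_mono) > 0) {
    msg <- "Labels decrease across horizons for {length(non_mono)} record{?s}: {.val {non_mono}}."
    if (monotonicity == "error") stop_validation(msg) else cli::cli_warn(msg)
  }
  invisible(outcomes)
}

#' Write an outcome-label table in the deposited layout
#'
#' @param outcomes Tibble with `record_id`, `T_180`, `T_360`, `T_720`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes[c("record_id", horizon_label_cols())], path)
  invisible(path)
}

# ---- human ratings ---------------------------------------------------------

#' Read human ratings (student questionnaires)
#'
#' Accepts either the normative long CSV layout with columns `rater_id`,
#' `record_id`, `horizon`, `score`, or (best effort) the deposited
#' questionnaire block layout: for each questionnaire, a row labelled
#' "questionnaire" carrying the rater id, a row labelled "Clinical report N"
#' listing the 50 record ids, and one row per horizon labelled
#' "Prediction @ 180/360/720" carrying the 0-5 scores.
#'
#' @inheritParams read_outcomes
#' @return A tibble with columns `rater_id`, `record_id`, `horizon`, `score`.
#' @export
read_human_predictions <- function(path, dialect = c("auto", "csv", "xlsx"),
                                   quiet = FALSE) {
  dialect <- match.arg(dialect)
  df <- read_table_any(path, dialect)
  long_cols <- c("rater_id", "record_id", "horizon", "score")
  if (all(long_cols %in% names(df))) {
    out <- tibble::as_tibble(df[long_cols])
    out$horizon <- as.integer(out$horizon)
    out$score <- as.numeric(out$score)
  } else {
    raw <- read_table_any(path, dialect, col_names = FALSE)
    out <- parse_questionnaire_blocks(raw)
  }
  validate_ratings(out)
  if (!quiet) {
    cli::cli_inform(
      "Read {nrow(out)} rating{?s} from {length(unique(out$rater_id))} rater{?s}.")
  }
  out
}

# Best-effort parser for the questionnaire block layout: scans the label
# column for "questionnaire", "clinical report" and "prediction @ <h>" rows.
parse_questionnaire_blocks <- function(raw) {
  m <- as.matrix(raw)
  labels <- tolower(trimws(as.character(m[, 1])))
  rows <- list()
  rater <- NULL
  records <- NULL
  for (i in seq_len(nrow(m))) {
    lab <- labels[[i]]
    if (is.na(lab) || lab == "") next
    if (grepl("^questionnaire", lab)) {
      rater <- as.character(m[i, 2])
      records <- NULL
    } else if (grepl("clinical report", lab)) {
      records <- suppressWarnings(as.numeric(m[i, -1]))
    } else if (grepl("^prediction", lab)) {
      h <- as.integer(sub(".*?(\\d+).*", "\\1", lab))
      scores <- suppressWarnings(as.numeric(m[i, -1]))
      keep <- !is.na(records) & !is.na(scores)
      if (is.null(rater) || is.null(records)) {
        stop_schema("Malformed questionnaire block near row {i}.")
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        rater_id = rater, record_id = records[keep],
        horizon = h, score = scores[keep])
    }
  }
  if (length(rows) == 0) {
    stop_schema(paste(
      "File matches neither the long rating layout",
      "(rater_id, record_id, horizon, score) nor the questionnaire block layout."))
  }
  dplyr::bind_rows(rows)
}

#' Validate a human-rating table
#'
#' Scores must be integers in 0..5 and each (rater, record, horizon) may
#' appear at most once.
#'
#' @param ratings Tibble with `rater_id`, `record_id`, `horizon`, `score`.
#' @return `ratings`, invisibly.
#' @export
validate_ratings <- function(ratings) {
  bad <- !is.finite(ratings$score) | ratings$score < 0 | ratings$score > 5 |
    ratings$score != round(ratings$score)
  if (any(bad)) {
    ids <- unique(ratings$record_id[bad])
    stop_validation(
      "Scores outside the integer 0..5 scale for {length(ids)} record{?s}: {.val {ids}}.")
  }
  key <- paste(ratings$rater_id, ratings$record_id, ratings$horizon)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_validation("{length(dup)} duplicate (rater, record, horizon) rating{?s}: {.val {dup}}.")
  }
  invisible(ratings)
}

#' Write human ratings in the long CSV layout
#'
#' @param ratings Tibble with `rater_id`, `record_id`, `horizon`, `score`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_human_predictions <- function(ratings, path) {
  readr::write_csv(ratings[c("rater_id", "record_id", "horizon", "score")], path)
  invisible(path)
}

# ---- machine ensemble scores -----------------------------------------------

#' Read per-record machine ensemble probabilities
#'
#' Reads a table in the deposited machine-score layout: one row per record
#' with probability columns `Score_180`, `Score_360`, `Score_720` in \[0, 1\].
#'
#' @inheritParams read_outcomes
#' @return A long tibble with columns `record_id`, `horizon`, `probability`.
#' @export
read_ensemble_predictions <- function(path, dialect = c("auto", "csv", "xlsx"),
                                      quiet = FALSE) {
  df <- read_table_any(path, match.arg(dialect))
  sc <- horizon_score_cols()
  missing <- setdiff(sc, names(df))
  if (length(missing) > 0) {
    stop_schema("Score file {.path {path}} lacks {length(missing)} column{?s}: {.val {missing}}.")
  }
  wide <- tibble::tibble(record_id = df[[find_record_col(df)]])
  for (col in sc) wide[[col]] <- as.numeric(df[[col]])
  out <- tidyr::pivot_longer(wide, dplyr::all_of(sc), names_to = "horizon",
                             names_prefix = "Score_", values_to = "probability")
  out$horizon <- as.integer(out$horizon)
  bad <- !is.finite(out$probability) | out$probability < 0 | out$probability > 1
  if (any(bad)) {
    ids <- unique(out$record_id[bad])
    stop_validation("Probabilities outside [0, 1] for {length(ids)} record{?s}: {.val {ids}}.")
  }
  if (!quiet) cli::cli_inform("Read scores for {length(unique(out$record_id))} record{?s}.")
  out
}

#' Write machine ensemble probabilities in the deposited layout
#'
#' @param scores Long tibble with `record_id`, `horizon`, `probability`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_predictions <- function(scores, path) {
  wide <- tidyr::pivot_wider(scores[c("record_id", "horizon", "probability")],
                             names_from = "horizon", values_from = "probability",
                             names_prefix = "Score_")
  readr::write_csv(wide[c("record_id", horizon_score_cols())], path)
  invisible(path)
}

# ---- results table ---------------------------------------------------------

#' Write a per-agent, per-horizon AUC results table
#'
#' Produces a CSV with one row per agent and one AUC column per horizon
#' (plus optional confidence-limit columns), mirroring the layout of a
#' published agent-by-horizon comparison table.
#'
#' @param results Long tibble with columns `agent`, `horizon`, `auc` and
#'   optionally `lower`, `upper`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop_validation("Results table is empty; nothing to write.")
  }
  need <- c("agent", "horizon", "auc")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0) stop_schema("Results lack {length(missing)} column{?s}: {.val {missing}}.")
  value_cols <- intersect(c("auc", "lower", "upper"), names(results))
  wide <- results %>%
    dplyr::mutate(agent = factor(.data$agent, levels = unique(.data$agent))) %>%
    dplyr::arrange(.data$agent, .data$horizon) %>%
    tidyr::pivot_wider(id_cols = "agent", names_from = "horizon",
                       values_from = dplyr::all_of(value_cols),
                       names_glue = "{.value}_{horizon}")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return A long tibble with `agent`, `horizon`, `auc` (and `lower`/`upper`
#'   when present).
#' @export
read_results_table <- function(path) {
  wide <- read_table_any(path, "csv")
  long <- tidyr::pivot_longer(wide, -"agent",
                              names_to = c(".value", "horizon"),
                              names_pattern = "(auc|lower|upper)_(\\d+)")
  long$horizon <- as.integer(long$horizon)
  dplyr::arrange(long, factor(.data$agent, levels = unique(wide$agent)), .data$horizon)
}
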