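# Internal helpers: error classes, seed substreams, column conventions.

stop_schema <- function(msg, ..., call = rlang::caller_env()) {
  cli::cli_abort(msg, ..., class = "mshybrid_schema_error", call = call, .envir = call)
}

stop_validation <- function(msg, ..., call = rlang::caller_env()) {
  cli::cli_abort(msg, ..., class = "mshybrid_validation_error", call = call, .envir = call)
}

stop_config <- function(msg, ..., call = rlang::caller_env()) {
  cli::cli_abort(msg, ..., class = "mshybrid_config_error", call = call, .envir = call)
}

stop_key <- function(msg, ..., call = rlang::caller_env()) {
  cli::cli_abort(msg, ..., class = "mshybrid_key_error", call = call, .envir = call)
}

#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (for example `"cohort"`, `"raters"`, `"ensemble"`), so that
#' regenerating one component never perturbs another.
#'
#' @param seed Master seed, a single integer.
#' @param label Substream name, a single string.
#' @return A single integer seed in `[1, 2147483562]`.
#' @export
#' @examples
#' substream_seed(42, "cohort")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1e6
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 7919) %% 2147483562) + 1L
}

# Feature columns of a visit-record table: everything that is not a key.
feature_cols <- function(records) {
  setdiff(names(records), c("record_id", "patient_id", "visit_index"))
}

# Column names of the deposited outcome layout, one per horizon.
horizon_label_cols <- function(horizons = HORIZONS) paste0("T_", horizons)

horizon_score_cols <- function(horizons = HORIZONS) paste0("Score_", horizons)

assert_horizon <- function(horizon) {
  if (!length(horizon) == 1 || !horizon %in% HORIZONS) {
    stop_config("{.arg horizon} must be one of {HORIZONS}, not {horizon}.")
  }
  as.integer(horizon)
}
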