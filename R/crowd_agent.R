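# Crowd aggregation of discrete human ratings into the three collective
# conditions: Singles (one AUC per rater), Pairs (mean of two randomly
# chosen ratings per record) and Group (mean of all ratings per record).

#' Normalize a 0-5 rating to the probability scale
#'
#' Ratings run from 0 ("extremely unlikely") to 5 ("highly probable") and
#' are mapped to \[0, 1\] by dividing by 5. Any strictly monotone map yields
#' identical AUCs; this one is fixed so that normalized ratings are
#' commensurate with machine probabilities in the hybrid combiner.
#'
#' @param score Integer vector with values in 0..5.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' normalize_rating(c(0, 3, 5))
normalize_rating <- function(score) {
  bad <- !is.finite(score) | score < 0 | score > 5 | score != round(score)
  if (any(bad)) {
    stop_validation("Scores outside the integer 0..5 scale: {.val {unique(score[bad])}}.")
  }
  score / 5
}

# Join ratings with labels at one horizon; returns rater_id, record_id,
# score (normalized) and label.
rated_labels <- function(ratings, outcomes, horizon) {
  horizon <- assert_horizon(horizon)
  lab_col <- paste0("T_", horizon)
  ratings %>%
    dplyr::filter(.data$horizon == !!horizon) %>%
    dplyr::inner_join(outcomes[c("record_id", lab_col)], by = "record_id") %>%
    dplyr::mutate(score = normalize_rating(.data$score),
                  label = .data[[lab_col]]) %>%
    dplyr::select("rater_id", "record_id", "score", "label")
}

#' Singles: one AUC per individual rater
#'
#' Computes each rater's tie-aware AUC on exactly the records that rater
#' scored. Raters whose rated records contain a single outcome class have
#' an undefined AUC; they are excluded from the mean and flagged in the
#' result rather than raising an error.
#'
#' @param ratings Long rating tibble (`rater_id`, `record_id`, `horizon`,
#'   `score`).
#' @param outcomes Outcome tibble (`record_id`, `T_180`, `T_360`, `T_720`).
#' @param horizon Horizon in days.
#' @return An object of class `crowd_singles`: `per_rater` tibble
#'   (`rater_id`, `auc`, `n`, `n_pos`, `eligible`), `mean`, `sd`,
#'   `n_eligible`, `n_excluded`, `horizon`.
#' @export
singles_auc <- function(ratings, outcomes, horizon) {
  df <- rated_labels(ratings, outcomes, horizon)
  if (nrow(df) == 0) stop_validation("No ratings at horizon {horizon}.")
  per_rater <- df %>%
    dplyr::group_by(.data$rater_id) %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_pos = sum(.data$label),
      eligible = n_pos > 0 && n_pos < n,
      auc = if (eligible) auc_rank(.data$score, .data$label) else NA_real_,
      .groups = "drop")
  excluded <- per_rater$rater_id[!per_rater$eligible]
  if (length(excluded) > 0) {
    cli::cli_inform(
      "Excluding {length(excluded)} rater{?s} with one-class labels: {.val {excluded}}.")
  }
  aucs <- per_rater$auc[per_rater$eligible]
  structure(list(per_rater = per_rater,
                 mean = mean(aucs), sd = sd(aucs),
                 n_eligible = length(aucs), n_excluded = length(excluded),
                 horizon = assert_horizon(horizon)),
            class = "crowd_singles")
}

#' @export
print.crowd_singles <- function(x, ...) {
  cli::cli_text(paste0(
    "<crowd_singles> {x$horizon} d: AUC {sprintf('%.2f ± %.2f', x$mean, x$sd)} ",
    "({x$n_eligible} rater{?s}, {x$n_excluded} excluded)"))
  invisible(x)
}

#' Pairs: AUC of two-rating averages
#'
#' Considers only records rated by at least two raters; where more ratings
#' are available, exactly two are chosen at random. The two normalized
#' ratings are averaged per record before the AUC is computed. The result
#' is stochastic; by default it is averaged over `n_draws` independent
#' random selections (the single-draw variant is `n_draws = 1`).
#'
#' @inheritParams singles_auc
#' @param n_draws Number of independent random 2-of-k selections to average
#'   over.
#' @param seed Integer seed.
#' @return An object of class `crowd_pairs`: `auc` (mean over draws),
#'   `draws` (per-draw AUCs), `n_records` (eligible records), `horizon`.
#' @export
pairs_auc <- function(ratings, outcomes, horizon, n_draws = 100, seed = 1) {
  df <- rated_labels(ratings, outcomes, horizon)
  eligible <- df %>%
    dplyr::group_by(.data$record_id) %>%
    dplyr::filter(dplyr::n() >= 2) %>%
    dplyr::ungroup()
  if (nrow(eligible) == 0) {
    stop_validation("No records with at least two ratings at horizon {horizon}.")
  }
  labels <- eligible %>% dplyr::distinct(.data$record_id, .data$label)
  check_binary_labels(labels$label)
  withr::local_seed(substream_seed(seed, "pairs"))

  scores_by_record <- split(eligible$score, eligible$record_id)
  label_by_record <- labels$label[match(names(scores_by_record),
                                        as.character(labels$record_id))]
  draws <- vapply(seq_len(n_draws), function(d) {
    means <- vapply(scores_by_record, function(s) {
      if (length(s) == 2) mean(s) else mean(sample(s, 2))
    }, numeric(1))
    auc_rank(means, label_by_record)
  }, numeric(1))
  structure(list(auc = mean(draws), draws = draws,
                 n_records = length(scores_by_record), n_draws = n_draws,
                 horizon = assert_horizon(horizon), seed = seed),
            class = "crowd_pairs")
}

#' @export
print.crowd_pairs <- function(x, ...) {
  cli::cli_text(paste0(
    "<crowd_pairs> {x$horizon} d: AUC {sprintf('%.3f', x$auc)} ",
    "(mean of {x$n_draws} draw{?s}, {x$n_records} record{?s})"))
  invisible(x)
}

#' Group: AUC of the all-rater average
#'
#' Averages all normalized ratings per record and computes the AUC over all
#' rated records. Deterministic. Records without any rating are excluded
#' and counted.
#'
#' @inheritParams singles_auc
#' @return An object of class `crowd_group`: `auc`, `scores` tibble
#'   (`record_id`, `score`, `dispersion`, `n_ratings`, `label`),
#'   `n_unrated`, `horizon`.
#' @export
group_auc <- function(ratings, outcomes, horizon) {
  df <- rated_labels(ratings, outcomes, horizon)
  if (nrow(df) == 0) stop_validation("No ratings at horizon {horizon}.")
  scores <- df %>%
    dplyr::group_by(.data$record_id) %>%
    dplyr::summarise(dispersion = if (dplyr::n() >= 2) sd(.data$score) else NA_real_,
                     score = mean(.data$score),
                     n_ratings = dplyr::n(),
                     label = .data$label[1], .groups = "drop")
  n_unrated <- nrow(outcomes) - nrow(scores)
  if (n_unrated > 0) {
    cli::cli_inform("{n_unrated} record{?s} without ratings excluded from Group AUC.")
  }
  check_binary_labels(scores$label)
  structure(list(auc = auc_rank(scores$score, scores$label), scores = scores,
                 n_unrated = n_unrated, horizon = assert_horizon(horizon)),
            class = "crowd_group")
}

#' @export
print.crowd_group <- function(x, ...) {
  cli::cli_text(paste0(
    "<crowd_group> {x$horizon} d: AUC {sprintf('%.3f', x$auc)} ",
    "({nrow(x$scores)} rated record{?s}, {x$n_unrated} unrated)"))
  invisible(x)
}
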