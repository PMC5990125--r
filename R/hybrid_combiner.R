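# Concordance-ranked hybrid combination of a human and a machine agent.
# Each agent's per-record dispersion of unitary predictions is converted to
# a normalized concordance rank (1 = most consistent, 0 = most scattered);
# squared ranks emphasize the more consistent agent when the two forecast
# means are combined.

#' Concordance statistic of a set of unitary predictions
#'
#' The sample standard deviation of the unitary predictions for one record:
#' zero exactly when all unitary predictions agree, growing as they
#' scatter. Smaller values mean higher concordance.
#'
#' @param unitary Numeric vector of at least 2 probabilities, or a list of
#'   such vectors (one element per record).
#' @return A single dispersion, or one per list element.
#' @export
#' @examples
#' concordance(c(0, 1))
concordance <- function(unitary) {
  if (is.list(unitary)) {
    return(vapply(unitary, concordance, numeric(1)))
  }
  if (length(unitary) < 2) {
    cli::cli_abort("Concordance undefined for fewer than 2 unitary predictions.",
                   class = "mshybrid_undefined_concordance")
  }
  sd(unitary)
}

#' Normalized concordance ranks
#'
#' Ranks records by dispersion (ascending, average ranks for ties) and
#' rescales the raw rank `R` in `1..N` to `(N - R) / (N - 1)`, so the most
#' concordant record (smallest dispersion) gets rank 1 and the most
#' scattered gets 0. When all dispersions are equal, every record gets
#' 0.5 and a warning is raised.
#'
#' @param dispersion Numeric vector of per-record dispersions (length >= 2).
#' @return Numeric vector of normalized ranks in \[0, 1\].
#' @export
#' @examples
#' concordance_ranks(c(0, 0.1, 0.2))
concordance_ranks <- function(dispersion) {
  n <- length(dispersion)
  if (n < 2) stop_config("Need at least 2 records to rank.")
  if (length(unique(dispersion)) == 1) {
    cli::cli_warn("All dispersions equal; every concordance rank set to 0.5.")
  }
  r <- rank(dispersion, ties.method = "average")
  (n - r) / (n - 1)
}

combine_means <- function(m_h, m_m, w_h, w_m) {
  total <- w_h + w_m
  out <- (w_h * m_h + w_m * m_m) / total
  out[total == 0] <- (m_h[total == 0] + m_m[total == 0]) / 2
  out
}

#' Hybrid combination of a human and a machine forecast
#'
#' Joins two per-record forecast tables (columns `record_id`, `mean`,
#' `dispersion`, and optionally `horizon`), computes each agent's
#' normalized concordance ranks per horizon over the shared record set, and
#' combines the two forecast means:
#'
#' * `"weighted"` (default): squared-rank-weighted average
#'   `(r_H^2 m_H + r_M^2 m_M) / (r_H^2 + r_M^2)`, falling back to the plain
#'   average when both squared ranks are zero. This uses the squared
#'   concordance ranks as consistency weights and preserves the forecast
#'   direction, so the score orders records for a ROC analysis.
#' * `"sum_sq_ranks"`: `r_H^2 + r_M^2`, the bare consistency score in
#'   \[0, 2\]. It carries no forecast direction (unanimous "no transition"
#'   and unanimous "transition" both rank high), so it is retained as a
#'   documented variant, not the default.
#' * `"linear_ranks"`: as `"weighted"` but with unsquared rank weights (a
#'   degraded ablation).
#' * `"unranked"`: inverse-dispersion weights without ranking (a degraded
#'   ablation); an agent with zero dispersion takes all the weight, equal
#'   split when both are zero.
#'
#' @param human,machine Forecast tibbles with `record_id`, `mean`,
#'   `dispersion` and optionally `horizon`.
#' @param mode Combination mode, see above.
#' @param strict If `TRUE`, records present in only one agent's table raise
#'   an error; by default they are dropped with a message.
#' @return A tibble with `record_id` (and `horizon` if supplied),
#'   `mean_human`, `mean_machine`, `rank_human`, `rank_machine`, `score`,
#'   `mode`.
#' @export
hybrid_score <- function(human, machine,
                         mode = c("weighted", "sum_sq_ranks", "linear_ranks",
                                  "unranked"),
                         strict = FALSE) {
  mode <- match.arg(mode)
  for (nm in c("record_id", "mean", "dispersion")) {
    if (!nm %in% names(human) || !nm %in% names(machine)) {
      stop_schema("Both forecast tables need column {.val {nm}}.")
    }
  }
  keys <- intersect(c("record_id", "horizon"), intersect(names(human), names(machine)))
  only_h <- dplyr::anti_join(human, machine, by = keys)
  only_m <- dplyr::anti_join(machine, human, by = keys)
  if (nrow(only_h) + nrow(only_m) > 0) {
    ids <- unique(c(only_h$record_id, only_m$record_id))
    if (strict) {
      stop_key("{length(ids)} record{?s} present for only one agent: {.val {ids}}.")
    }
    cli::cli_inform("Dropping {length(ids)} record{?s} present for only one agent.")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(human[c(keys, "mean", "dispersion")],
                  mean_human = "mean", disp_human = "dispersion"),
    dplyr::rename(machine[c(keys, "mean", "dispersion")],
                  mean_machine = "mean", disp_machine = "dispersion"),
    by = keys)
  if (nrow(joined) < 2) stop_validation("Fewer than 2 shared records to combine.")

  joined %>%
    dplyr::group_by(dplyr::across(dplyr::any_of("horizon"))) %>%
    dplyr::mutate(
      rank_human = concordance_ranks(.data$disp_human),
      rank_machine = concordance_ranks(.data$disp_machine),
      score = switch(
        mode,
        weighted = combine_means(.data$mean_human, .data$mean_machine,
                                 .data$rank_human^2, .data$rank_machine^2),
        sum_sq_ranks = .data$rank_human^2 + .data$rank_machine^2,
        linear_ranks = combine_means(.data$mean_human, .data$mean_machine,
                                     .data$rank_human, .data$rank_machine),
        unranked = combine_means(
          .data$mean_human, .data$mean_machine,
          inverse_dispersion_weight(.data$disp_human, .data$disp_machine),
          inverse_dispersion_weight(.data$disp_machine, .data$disp_human))
      ),
      mode = mode) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(keys), "mean_human", "mean_machine",
                  "rank_human", "rank_machine", "score", "mode")
}

# Inverse-dispersion weight for the unranked ablation; a zero-dispersion
# agent gets all the weight (1 vs 0), equal split when both are zero.
inverse_dispersion_weight <- function(d_self, d_other) {
  w <- ifelse(d_self == 0, ifelse(d_other == 0, 1, Inf), 1 / d_self)
  both <- is.infinite(w)
  w[both] <- 1
  other_zero <- d_other == 0 & d_self > 0
  w[other_zero] <- 0
  w
}
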