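# Independent oracles and small fixture builders shared across tests.

# O(n^2) pair-count AUC: concordant pairs count 1, tied scores count 1/2.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Two-pass sample standard deviation, independent of stats::sd.
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Sort-based normalized concordance ranking (no ties expected in inputs).
sort_rank_oracle <- function(dispersion) {
  n <- length(dispersion)
  raw <- match(seq_len(n), order(dispersion))  # 1 = smallest dispersion
  (n - raw) / (n - 1)
}

# Small cohort for fast protocol tests.
small_cohort <- function(seed = 1, n_patients = 12, signal = 1) {
  simulate_cohort(
    cohort_config(n_patients = n_patients, n_features = 3,
                  signal_strength = signal),
    seed = seed)
}

labels_for <- function(cohort, ids, horizon) {
  cohort$outcomes[[paste0("T_", horizon)]][
    match(ids, cohort$outcomes$record_id)]
}

# A tiny deterministic rating table: each rater scores each record once per
# horizon with the given score matrix (raters x records).
ratings_from_matrix <- function(scores, horizon = 180) {
  stopifnot(is.matrix(scores))
  tidyr::expand_grid(rater = seq_len(nrow(scores)),
                     record = seq_len(ncol(scores))) %>%
    dplyr::mutate(rater_id = paste0("R", rater), record_id = record,
                  horizon = horizon,
                  score = scores[cbind(rater, record)]) %>%
    dplyr::select(rater_id, record_id, horizon, score)
}

outcomes_from_labels <- function(labels, horizon = 180) {
  out <- tibble::tibble(record_id = seq_along(labels),
                        T_180 = 0, T_360 = 0, T_720 = 0)
  for (h in c(180, 360, 720)) {
    if (h >= horizon) out[[paste0("T_", h)]] <- labels
  }
  out
}
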