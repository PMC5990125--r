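# broom-style tidy()/glance() methods for the package's result objects.

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname bootstrap_auc
#' @param x A `bootstrap_summary`.
#' @param ... Unused.
#' @export
tidy.bootstrap_summary <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates), auc = x$replicates)
}

#' @rdname bootstrap_auc
#' @export
glance.bootstrap_summary <- function(x, ...) {
  tibble::tibble(auc = x$point_auc, lower = x$ci[1], upper = x$ci[2],
                 q1 = x$quartiles[1], median = x$quartiles[2],
                 q3 = x$quartiles[3], min = x$range[1], max = x$range[2],
                 level = x$level, n_boot = x$n_boot, n_redrawn = x$n_redrawn,
                 unit = x$unit)
}

#' @rdname auc_difference
#' @param x An `auc_difference`.
#' @param ... Unused.
#' @export
tidy.auc_difference <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates), delta = x$replicates)
}

#' @rdname auc_difference
#' @export
glance.auc_difference <- function(x, ...) {
  tibble::tibble(delta = x$delta, auc_a = x$auc_a, auc_b = x$auc_b,
                 lower = x$ci[1], upper = x$ci[2], level = x$level,
                 p_value = x$p_value, significant = x$significant,
                 n_boot = x$n_boot)
}

#' @rdname singles_auc
#' @param x A `crowd_singles`.
#' @param ... Unused.
#' @export
tidy.crowd_singles <- function(x, ...) x$per_rater

#' @rdname singles_auc
#' @export
glance.crowd_singles <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean, sd_auc = x$sd, n_eligible = x$n_eligible,
                 n_excluded = x$n_excluded, horizon = x$horizon)
}

#' @rdname pairs_auc
#' @param x A `crowd_pairs`.
#' @param ... Unused.
#' @export
tidy.crowd_pairs <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$draws), auc = x$draws)
}

#' @rdname pairs_auc
#' @export
glance.crowd_pairs <- function(x, ...) {
  tibble::tibble(auc = x$auc, sd_draws = sd(x$draws), n_records = x$n_records,
                 n_draws = x$n_draws, horizon = x$horizon)
}

#' @rdname group_auc
#' @param x A `crowd_group`.
#' @param ... Unused.
#' @export
tidy.crowd_group <- function(x, ...) x$scores

#' @rdname group_auc
#' @export
glance.crowd_group <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_records = nrow(x$scores),
                 n_unrated = x$n_unrated, horizon = x$horizon)
}

#' @rdname run_experiment
#' @param x A `hybrid_experiment`.
#' @param ... Unused.
#' @export
tidy.hybrid_experiment <- function(x, ...) x$results

#' @rdname run_experiment
#' @export
glance.hybrid_experiment <- function(x, ...) {
  tibble::tibble(mode = x$manifest$mode, seed = x$manifest$seed,
                 n_boot = x$manifest$n_boot,
                 hybrid_mode = x$manifest$hybrid_mode,
                 horizons = paste(x$manifest$horizons, collapse = "/"))
}
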