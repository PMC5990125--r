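# ROC/AUC evaluation: tie-aware Mann-Whitney AUC, percentile-bootstrap
# confidence intervals (record- or patient-level resampling), and paired
# bootstrap tests for AUC differences.

check_binary_labels <- function(labels, call = rlang::caller_env()) {
  if (any(!labels %in% c(0, 1))) {
    stop_validation("Labels must be binary 0/1.", call = call)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    cli::cli_abort(
      "AUC undefined: {n_pos} positive{?s} and {n_neg} negative{?s}.",
      class = "mshybrid_undefined_auc", n_pos = n_pos, n_neg = n_neg,
      call = call)
  }
  c(n_pos = n_pos, n_neg = n_neg)
}

# Rank (Mann-Whitney) AUC with half-credit for ties; no validation.
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC with half-credit for ties
#'
#' Computes the area under the receiver-operating-characteristic curve via
#' the Mann-Whitney pair formulation, counting tied scores as half
#' concordant, together with the tie-aware ROC curve (one point per distinct
#' score, ties collapsed), whose trapezoidal area equals the rank AUC.
#'
#' @param scores Numeric prediction scores (any monotone scale).
#' @param labels Binary 0/1 outcome labels, same length.
#' @return An object of class `roc_result`: `auc`, `n_pos`, `n_neg`, and a
#'   `curve` tibble with `threshold`, `fpr`, `tpr`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_validation("{.arg scores} and {.arg labels} differ in length.")
  }
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  counts <- check_binary_labels(labels)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / counts[["n_neg"]]),
    tpr = c(0, tp[last] / counts[["n_pos"]])
  )
  structure(list(auc = auc_rank(scores, labels),
                 n_pos = counts[["n_pos"]], n_neg = counts[["n_neg"]],
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cli::cli_text("<roc_result> AUC = {sprintf('%.4f', x$auc)} ({x$n_pos} pos / {x$n_neg} neg)")
  invisible(x)
}

resample_indices <- function(n, unit, patient_id) {
  if (unit == "record") {
    sample.int(n, n, replace = TRUE)
  } else {
    ids <- unique(patient_id)
    picked <- sample(ids, length(ids), replace = TRUE)
    unlist(lapply(picked, function(p) which(patient_id == p)), use.names = FALSE)
  }
}

#' Percentile-bootstrap distribution of the AUC
#'
#' Resamples the dataset with replacement (`unit = "record"`, the default,
#' resamples records; `unit = "patient"` resamples whole patients, a
#' robustness option for clustered records) and recomputes the tie-aware
#' AUC on each resample. Resamples containing a single outcome class are
#' redrawn so that exactly `n_boot` replicates are returned; the number of
#' redraws is recorded. Reports the percentile confidence interval,
#' quartiles, and the full replicate range (box-plot semantics: boxes =
#' quartiles, whiskers = full range).
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_boot Number of bootstrap replicates (at least 2).
#' @param level Confidence level for the percentile interval.
#' @param unit Resampling unit, `"record"` or `"patient"`.
#' @param patient_id Required when `unit = "patient"`.
#' @param seed Integer seed.
#' @return An object of class `bootstrap_summary`: `point_auc`,
#'   `replicates`, `quartiles` (q1, median, q3), `ci`, `level`, `n_boot`,
#'   `n_redrawn`, `seed`.
#' @export
bootstrap_auc <- function(scores, labels, n_boot = 1000, level = 0.95,
                          unit = c("record", "patient"), patient_id = NULL,
                          seed = 1) {
  unit <- match.arg(unit)
  if (n_boot < 2) stop_config("{.arg n_boot} must be at least 2.")
  if (unit == "patient" && is.null(patient_id)) {
    stop_config("{.arg patient_id} is required when {.code unit = \"patient\"}.")
  }
  point <- roc_auc(scores, labels)
  withr::local_seed(substream_seed(seed, "bootstrap"))

  n <- length(scores)
  replicates <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- resample_indices(n, unit, patient_id)
      y <- labels[idx]
      if (any(y == 1) && any(y == 0)) break
      n_redrawn <- n_redrawn + 1L
    }
    replicates[b] <- auc_rank(scores[idx], y)
  }
  alpha <- (1 - level) / 2
  structure(list(
    point_auc = point$auc,
    replicates = replicates,
    quartiles = quantile(replicates, c(0.25, 0.5, 0.75), names = FALSE),
    ci = quantile(replicates, c(alpha, 1 - alpha), names = FALSE),
    range = range(replicates),
    level = level, n_boot = as.integer(n_boot),
    n_redrawn = n_redrawn, unit = unit, seed = seed
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cli::cli_text(paste0(
    "<bootstrap_summary> AUC = {sprintf('%.4f', x$point_auc)}, ",
    "{sprintf('%.0f%%', 100 * x$level)} CI [{sprintf('%.4f', x$ci[1])}, ",
    "{sprintf('%.4f', x$ci[2])}] ({x$n_boot} resamples/{x$unit})"))
  invisible(x)
}

#' Paired bootstrap test for a difference in AUC
#'
#' Applies the same resample indices to two score vectors over the same
#' records, recomputing `AUC_a - AUC_b` on each replicate. Reports the
#' point difference, the percentile confidence interval, whether the
#' interval excludes zero (significance read from confidence limits), and a
#' two-sided bootstrap p-value from the replicate distribution's tail mass
#' at zero.
#'
#' @param scores_a,scores_b Score vectors over the same records. When both
#'   are named, names must agree (order-insensitive).
#' @inheritParams bootstrap_auc
#' @return An object of class `auc_difference`: `delta`, `auc_a`, `auc_b`,
#'   `ci`, `p_value`, `significant`, `replicates`.
#' @export
auc_difference <- function(scores_a, scores_b, labels, n_boot = 1000,
                           level = 0.95, unit = c("record", "patient"),
                           patient_id = NULL, seed = 1) {
  unit <- match.arg(unit)
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    extra <- c(setdiff(names(scores_a), names(scores_b)),
               setdiff(names(scores_b), names(scores_a)))
    if (length(extra) > 0) {
      stop_key("Score vectors cover different records: {.val {unique(extra)}}.")
    }
    scores_b <- scores_b[names(scores_a)]
  }
  if (length(scores_a) != length(scores_b)) {
    stop_key("Score vectors differ in length ({length(scores_a)} vs {length(scores_b)}).")
  }
  if (n_boot < 2) stop_config("{.arg n_boot} must be at least 2.")
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  withr::local_seed(substream_seed(seed, "auc-difference"))

  n <- length(labels)
  replicates <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- resample_indices(n, unit, patient_id)
      y <- labels[idx]
      if (any(y == 1) && any(y == 0)) break
    }
    replicates[b] <- auc_rank(scores_a[idx], y) - auc_rank(scores_b[idx], y)
  }
  alpha <- (1 - level) / 2
  ci <- quantile(replicates, c(alpha, 1 - alpha), names = FALSE)
  p <- min(1, 2 * min(mean(replicates <= 0), mean(replicates >= 0)))
  structure(list(
    delta = auc_a - auc_b, auc_a = auc_a, auc_b = auc_b,
    ci = ci, level = level, p_value = p,
    significant = ci[1] > 0 || ci[2] < 0,
    replicates = replicates, n_boot = as.integer(n_boot), seed = seed
  ), class = "auc_difference")
}

#' @export
print.auc_difference <- function(x, ...) {
  cli::cli_text(paste0(
    "<auc_difference> dAUC = {sprintf('%+.4f', x$delta)}, ",
    "{sprintf('%.0f%%', 100 * x$level)} CI [{sprintf('%.4f', x$ci[1])}, ",
    "{sprintf('%.4f', x$ci[2])}], p = {format.pval(x$p_value, digits = 3)}"))
  invisible(x)
}
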