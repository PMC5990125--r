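# The modified leave-one-out ensemble protocol. For each patient in turn,
# all of that patient's visits are excluded; n_sets training sets are
# built, each containing exactly one randomly chosen visit per remaining
# patient; one model is trained per set; the excluded patient's visits are
# scored by every model and the per-record probabilities averaged. The
# design prevents leakage between correlated same-patient records.

#' Build the training-set plan for one excluded patient
#'
#' Draws `n_sets` training sets, each containing exactly one randomly
#' chosen visit record per remaining patient (so with 84 patients every set
#' has 83 records). Visit choices are independent across sets and
#' patients. The excluded patient's records appear in no set.
#'
#' @param records Visit-record tibble with `record_id` and `patient_id`.
#' @param excluded_patient Patient whose records are withheld.
#' @param n_sets Number of training sets.
#' @param seed Integer seed; the plan is a deterministic function of
#'   `(seed, excluded_patient)`, so it does not depend on the order in
#'   which patients are processed.
#' @return An object of class `training_set_plan`: a tibble with `set_id`
#'   and `record_id`, with the excluded patient recorded as an attribute.
#' @export
build_training_sets <- function(records, excluded_patient, n_sets = 50, seed = 1) {
  patients <- unique(records$patient_id)
  if (!excluded_patient %in% patients) {
    stop_key("Patient {.val {excluded_patient}} not present in the records.")
  }
  if (length(patients) < 2) {
    stop_config("Need at least 2 patients to build training sets.")
  }
  remaining <- sort(setdiff(patients, excluded_patient))  # order-invariant RNG use
  by_patient <- lapply(split(records$record_id, records$patient_id)[remaining], sort)
  withr::local_seed(substream_seed(seed, paste0("plan-", excluded_patient)))
  sets <- purrr::map_dfr(seq_len(n_sets), function(s) {
    picks <- vapply(by_patient,
                    function(ids) ids[sample.int(length(ids), 1)],
                    ids_prototype(records$record_id))
    tibble::tibble(set_id = s, record_id = unname(picks))
  })
  structure(sets, excluded_patient = excluded_patient,
            n_sets = as.integer(n_sets),
            class = c("training_set_plan", class(sets)))
}

ids_prototype <- function(ids) if (is.numeric(ids)) numeric(1) else character(1)

#' Random-forest base learner for the leave-one-out protocol
#'
#' Returns the learner contract used by [fit_predict_loo()]: a `fit(x, y)`
#' function and a `predict_probability(model, x)` function returning
#' class-1 probabilities in \[0, 1\]. A probability forest with
#' `num_trees` trees (100 by default) is trained; a training set containing
#' a single outcome class yields a constant model predicting that class's
#' probability (0 or 1), so every record always receives a full set of
#' unitary predictions.
#'
#' @param num_trees Number of trees.
#' @param mtry Optional variables per split (ranger default when `NULL`).
#' @return A list with elements `fit`, `predict_probability`, `label`.
#' @export
rf_learner <- function(num_trees = 100, mtry = NULL) {
  list(
    fit = function(x, y) {
      if (length(unique(y)) == 1) {
        return(structure(list(constant = y[[1]]), class = "mshybrid_constant_model"))
      }
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
      ranger::ranger(.y ~ ., data = df, num.trees = num_trees, mtry = mtry,
                     probability = TRUE, num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1))
    },
    predict_probability = function(model, x) {
      if (inherits(model, "mshybrid_constant_model")) {
        return(rep(as.numeric(model$constant), nrow(x)))
      }
      stats::predict(model, data = data.frame(x, check.names = FALSE),
                     num.threads = 1)$predictions[, "1"]
    },
    label = sprintf("ranger probability forest (%d trees)", num_trees)
  )
}

#' Constant base learner
#'
#' Predicts the same probability for every record; useful for testing the
#' protocol's plumbing (its forecasts have zero dispersion by construction).
#'
#' @param probability The constant class-1 probability.
#' @return A learner contract as in [rf_learner()].
#' @export
constant_learner <- function(probability = 0.5) {
  list(
    fit = function(x, y) structure(list(constant = probability),
                                   class = "mshybrid_constant_model"),
    predict_probability = function(model, x) rep(model$constant, nrow(x)),
    label = sprintf("constant %.2f", probability)
  )
}

# Median imputation: medians computed on the training block only, applied
# to both blocks (no leakage; all-NA training columns fall back to 0).
impute_median <- function(train, test) {
  med <- apply(train, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), test = fill(test))
}

#' Leave-one-patient-out ensemble forecasts
#'
#' Runs the modified leave-one-out protocol at one horizon: for every
#' patient, trains `n_sets` models (one per training set from
#' [build_training_sets()], none containing any of that patient's records)
#' and scores all of the patient's visits with each, keeping the `n_sets`
#' unitary probabilities, their mean and their dispersion (sample standard
#' deviation) per record. Missing feature values are imputed with medians
#' computed within each training set only. Results are invariant to the
#' order in which patients are processed (one random substream per
#' excluded patient and training set).
#'
#' @param records Visit-record tibble (`record_id`, `patient_id`,
#'   `visit_index`, feature columns).
#' @param outcomes Outcome tibble in the deposited layout.
#' @param horizon Horizon in days.
#' @param base_learner A learner contract, see [rf_learner()].
#' @param n_sets Number of training sets (and unitary predictions) per
#'   excluded patient.
#' @param seed Integer master seed.
#' @return A forecast tibble: `record_id`, `horizon`, `mean`, `dispersion`,
#'   list-column `unitary` (length `n_sets` each).
#' @export
fit_predict_loo <- function(records, outcomes, horizon,
                            base_learner = rf_learner(), n_sets = 50,
                            seed = 1) {
  horizon <- assert_horizon(horizon)
  lab_col <- paste0("T_", horizon)
  if (!lab_col %in% names(outcomes)) {
    stop_schema("Outcomes lack column {.val {lab_col}}.")
  }
  feats <- feature_cols(records)
  x_all <- as.matrix(records[feats])
  rownames(x_all) <- as.character(records$record_id)
  y_all <- outcomes[[lab_col]][match(records$record_id, outcomes$record_id)]
  if (anyNA(y_all)) stop_key("Some records have no outcome label at {horizon} d.")

  patients <- unique(records$patient_id)
  forecasts <- purrr::map_dfr(patients, function(p) {
    test_rows <- which(records$patient_id == p)
    plan <- build_training_sets(records, p, n_sets = n_sets, seed = seed)
    probs <- vapply(seq_len(n_sets), function(s) {
      train_rows <- match(plan$record_id[plan$set_id == s], records$record_id)
      withr::with_seed(
        substream_seed(seed, paste0("fit-", p, "-", s)), {
          xs <- impute_median(x_all[train_rows, , drop = FALSE],
                              x_all[test_rows, , drop = FALSE])
          model <- base_learner$fit(xs$train, y_all[train_rows])
          base_learner$predict_probability(model, xs$test)
        })
    }, numeric(length(test_rows)))
    probs <- matrix(probs, nrow = length(test_rows))
    tibble::tibble(
      record_id = records$record_id[test_rows],
      horizon = horizon,
      mean = rowMeans(probs),
      dispersion = apply(probs, 1, sd),
      unitary = lapply(seq_len(nrow(probs)), function(i) unname(probs[i, ]))
    )
  })
  dplyr::arrange(forecasts, .data$record_id)
}
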