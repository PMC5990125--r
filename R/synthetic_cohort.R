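# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: patients with multiple visits, an absorbing RR->SP
# transition driven by a log-linear hazard in a latent risk, per-horizon
# binary labels, noisy signal-bearing features, human raters on a 0-5 scale,
# and machine-like ensembles whose per-record dispersion grows on hard
# records. None of the clinical variables of real MS cohorts are modelled;
# only the signal/noise/dispersion structure the downstream stages exploit.

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the shape of the study cohort this package targets:
#' 84 patients, about 527 visits in total (mean 6.27 visits per patient,
#' truncated-geometric), visits roughly three times a year, and per-horizon
#' transition prevalences near 12.3%, 23.7% and 40.0% at 180, 360 and 720
#' days. The transition time from a patient's last recorded visit is
#' exponential with rate `exp(risk_slope * risk) / hazard_scale`, where
#' `risk` is a standard-normal patient-level latent; `hazard_scale` is in
#' days. Features are affine in the latent risk with independent Gaussian
#' noise of standard deviation `1 / signal_strength`.
#'
#' @param n_patients Number of patients (at least 2).
#' @param mean_visits Mean of the truncated-geometric visits-per-patient
#'   distribution.
#' @param max_visits Upper truncation of the visit count.
#' @param visit_spacing Days between consecutive visits.
#' @param n_features Number of feature columns.
#' @param signal_strength Feature signal-to-noise control; noise sd is
#'   `1 / signal_strength`. `Inf` gives noiseless, perfectly separable
#'   features.
#' @param risk_slope Log-hazard slope on the latent risk.
#' @param hazard_scale Baseline time scale of the transition hazard, days.
#' @param horizons Prediction horizons in days.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 84,
                          mean_visits = 527 / 84,
                          max_visits = 15,
                          visit_spacing = 103,
                          n_features = 8,
                          signal_strength = 1,
                          risk_slope = 3.22,
                          hazard_scale = 880,
                          horizons = HORIZONS) {
  if (n_patients < 2) stop_config("{.arg n_patients} must be at least 2.")
  if (mean_visits < 1) stop_config("{.arg mean_visits} must be at least 1.")
  if (!is.finite(hazard_scale) && !identical(hazard_scale, Inf) || hazard_scale <= 0) {
    stop_config("{.arg hazard_scale} must be positive (possibly Inf).")
  }
  if (signal_strength < 0) stop_config("{.arg signal_strength} must be non-negative.")
  structure(list(
    n_patients = as.integer(n_patients), mean_visits = mean_visits,
    max_visits = as.integer(max_visits), visit_spacing = visit_spacing,
    n_features = as.integer(n_features), signal_strength = signal_strength,
    risk_slope = risk_slope, hazard_scale = hazard_scale,
    horizons = as.integer(horizons)
  ), class = "cohort_config")
}

#' Configuration of a panel of simulated human raters
#'
#' Defaults mirror the rating design this package targets: 42 raters, each
#' scoring 50 records drawn without replacement, on a discrete 0-5 scale.
#' `skill` interpolates each rating between the record's true per-horizon
#' transition probability (`skill = 1`: noiseless) and uniform noise
#' (`skill = 0`); `dispersion_coupling` inflates the noise on hard records
#' (those whose true probability is close to 0.5), so that rater
#' disagreement carries information about correctness.
#'
#' @param n_raters Number of raters.
#' @param records_per_rater Records scored by each rater.
#' @param skill Signal weight in \[0, 1\].
#' @param dispersion_coupling Non-negative hardness multiplier on the noise.
#' @return A `rater_config` list.
#' @export
rater_config <- function(n_raters = 42, records_per_rater = 50,
                         skill = 0.15, dispersion_coupling = 1) {
  if (n_raters < 1) stop_config("{.arg n_raters} must be at least 1.")
  if (skill < 0 || skill > 1) stop_config("{.arg skill} must be in [0, 1].")
  if (dispersion_coupling < 0) stop_config("{.arg dispersion_coupling} must be >= 0.")
  structure(list(
    n_raters = as.integer(n_raters),
    records_per_rater = as.integer(records_per_rater),
    skill = skill, dispersion_coupling = dispersion_coupling
  ), class = "rater_config")
}

# Truncated-geometric visit-count pmf on 1..max_visits with the configured mean.
visit_count_pmf <- function(config) {
  q <- 1 / config$mean_visits
  pn <- dgeom(seq_len(config$max_visits) - 1L, q)
  pn / sum(pn)
}

#' Simulate a synthetic cohort of visit records
#'
#' Draws a patient-level latent risk, a transition time from the last visit
#' under the log-linear hazard (so every recorded visit happens in the RR
#' phase, and several patients transition only after their last visit),
#' per-visit features, and per-horizon binary labels. Labels are monotone
#' non-decreasing in horizon by construction (the SP phase is absorbing).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `ms_cohort` with tibbles
#'   * `records`: `record_id`, `patient_id`, `visit_index`, feature columns
#'     `feat_*`;
#'   * `outcomes`: `record_id`, `T_180`, `T_360`, `T_720`;
#'   * `truth`: per-record `record_id`, `patient_id`, `risk`,
#'     `time_to_transition` (days from the visit), `hardness` and the true
#'     per-horizon transition probabilities `p_180`, `p_360`, `p_720`;
#'   * `patients`: `patient_id`, `risk`, `transition_time` (days from first
#'     visit), `n_visits`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  withr::local_seed(substream_seed(seed, "cohort"))

  pn <- visit_count_pmf(config)
  n_visits <- sample.int(config$max_visits, config$n_patients,
                         replace = TRUE, prob = pn)
  risk <- rnorm(config$n_patients)
  lambda <- exp(config$risk_slope * risk) / config$hazard_scale
  resid <- rexp(config$n_patients, rate = pmax(lambda, .Machine$double.xmin))
  if (identical(config$hazard_scale, Inf)) resid <- rep(Inf, config$n_patients)

  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(config$n_patients)),
    risk = risk, n_visits = n_visits,
    transition_time = (n_visits - 1) * config$visit_spacing + resid
  )

  idx <- rep(seq_len(config$n_patients), n_visits)
  visit_index <- sequence(n_visits)
  offset <- (n_visits[idx] - visit_index) * config$visit_spacing
  time_to_transition <- resid[idx] + offset
  n_rec <- length(idx)

  labels <- vapply(config$horizons,
                   function(h) as.integer(time_to_transition <= h),
                   integer(n_rec))
  probs <- vapply(config$horizons, function(h) {
    1 - exp(-lambda[idx] * pmax(0, h - offset))
  }, numeric(n_rec))
  hardness <- 1 - 2 * abs(rowMeans(probs) - 0.5)

  noise_sd <- if (is.infinite(config$signal_strength)) 0 else 1 / config$signal_strength
  slopes <- seq(0.5, 1.5, length.out = config$n_features)
  feats <- sapply(seq_len(config$n_features), function(k) {
    slopes[k] * risk[idx] + rnorm(n_rec, sd = noise_sd)
  })
  colnames(feats) <- sprintf("feat_%02d", seq_len(config$n_features))

  records <- tibble::tibble(
    record_id = seq_len(n_rec),
    patient_id = patients$patient_id[idx],
    visit_index = visit_index
  ) %>% dplyr::bind_cols(tibble::as_tibble(feats))

  outcomes <- tibble::tibble(record_id = records$record_id)
  for (i in seq_along(config$horizons)) {
    outcomes[[paste0("T_", config$horizons[i])]] <- labels[, i]
  }

  truth <- tibble::tibble(
    record_id = records$record_id, patient_id = records$patient_id,
    risk = risk[idx], time_to_transition = time_to_transition,
    hardness = hardness
  )
  for (i in seq_along(config$horizons)) {
    truth[[paste0("p_", config$horizons[i])]] <- probs[, i]
  }

  structure(list(records = records, outcomes = outcomes, truth = truth,
                 patients = patients, config = config, seed = seed),
            class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cli::cli_text("<ms_cohort> {nrow(x$records)} records, {nrow(x$patients)} patients")
  prev <- colMeans(x$outcomes[horizon_label_cols(x$config$horizons)])
  cli::cli_text("prevalence: {paste(sprintf('%s d: %.1f%%', x$config$horizons, 100 * prev), collapse = ', ')}")
  invisible(x)
}

#' Closed-form expected record-level prevalence of the generator
#'
#' Integrates the transition probability `1 - exp(-lambda(u) * (h - d)^+)`
#' over the standard-normal latent risk and the truncated-geometric visit
#' structure, weighting each visit offset `d` from the last visit by its
#' frequency among records. This is the analytic expectation against which
#' the simulator is validated.
#'
#' @param config A [cohort_config()].
#' @param horizon Horizon in days (defaults to all configured horizons).
#' @return Named numeric vector of expected prevalences.
#' @export
expected_prevalence <- function(config = cohort_config(), horizon = config$horizons) {
  pn <- visit_count_pmf(config)
  one <- function(h) {
    num <- 0
    for (n in seq_len(config$max_visits)) {
      for (j in seq_len(n)) {
        hh <- h - (n - j) * config$visit_spacing
        if (hh > 0) {
          f <- function(u) {
            (1 - exp(-exp(config$risk_slope * u) / config$hazard_scale * hh)) * dnorm(u)
          }
          num <- num + pn[n] * integrate(f, -8, 8)$value
        }
      }
    }
    num / sum(pn * seq_len(config$max_visits))
  }
  setNames(vapply(horizon, one, numeric(1)), paste0("T_", horizon))
}

#' Simulate a panel of human raters
#'
#' Each rater scores `records_per_rater` records, drawn without replacement,
#' at every horizon. The latent rating is
#' `skill * p + (1 - skill) * noise`, where `p` is the record's true
#' per-horizon transition probability and the uniform noise is stretched
#' around 0.5 by `1 + dispersion_coupling * hardness` (then clipped to
#' \[0, 1\]), and is discretized to the 0-5 scale by equal-width bins.
#'
#' @param cohort An `ms_cohort` from [simulate_cohort()].
#' @param config A [rater_config()].
#' @param seed Integer seed.
#' @return A tibble of ratings: `rater_id`, `record_id`, `horizon`, `score`.
#' @export
simulate_raters <- function(cohort, config = rater_config(), seed = 1) {
  stopifnot(inherits(cohort, "ms_cohort"), inherits(config, "rater_config"))
  n_rec <- nrow(cohort$records)
  if (n_rec == 0) stop_config("Cohort has no records.")
  if (config$records_per_rater > n_rec) {
    stop_config("{.arg records_per_rater} ({config$records_per_rater}) exceeds the {n_rec} available records.")
  }
  withr::local_seed(substream_seed(seed, "raters"))

  assignments <- purrr::map_dfr(seq_len(config$n_raters), function(r) {
    tibble::tibble(
      rater_id = sprintf("S%02d", r),
      record_id = sort(sample(cohort$records$record_id, config$records_per_rater))
    )
  })
  horizons <- cohort$config$horizons
  long <- tidyr::expand_grid(assignments, horizon = horizons) %>%
    dplyr::left_join(
      tidyr::pivot_longer(cohort$truth[c("record_id", "hardness",
                                         paste0("p_", horizons))],
                          dplyr::starts_with("p_"), names_to = "horizon",
                          names_prefix = "p_", values_to = "p") %>%
        dplyr::mutate(horizon = as.integer(.data$horizon)),
      by = c("record_id", "horizon"))

  eta <- runif(nrow(long))
  stretch <- 1 + config$dispersion_coupling * long$hardness
  noise <- pmin(pmax(0.5 + stretch * (eta - 0.5), 0), 1)
  z <- config$skill * long$p + (1 - config$skill) * noise
  long$score <- pmin(floor(z * 6), 5)
  out <- long[c("rater_id", "record_id", "horizon", "score")]
  validate_ratings(out)
  out
}

#' Simulate a machine-like ensemble agent
#'
#' For every record and horizon, draws `n_unitary` probabilities around a
#' skill-weighted anchor `w * y + (1 - w) * eta`, where `y` is the realized
#' label, `eta` a per-record uniform draw, and the effective signal weight
#' `w = skill^(1 + dispersion_coupling * hardness)` decays on hard records.
#' The unitary spread is Gaussian with standard deviation
#' `noise_sd * (1 + dispersion_coupling * hardness)`, clipped to \[0, 1\].
#' With `skill = 1` the averaged forecast separates the classes perfectly;
#' with `skill = 0` it is uninformative. With `dispersion_coupling > 0`,
#' hard records get both a weaker anchor (higher misclassification
#' probability) and a larger per-record dispersion - the
#' dispersion-correctness coupling the concordance-ranked hybrid combiner
#' exploits.
#'
#' @param cohort An `ms_cohort`.
#' @param n_unitary Number of unitary predictions per record (at least 2).
#' @param skill Signal weight in \[0, 1\].
#' @param dispersion_coupling Non-negative hardness multiplier on the spread.
#' @param noise_sd Baseline spread of the unitary predictions.
#' @param seed Integer seed.
#' @return A forecast tibble: `record_id`, `horizon`, `mean`, `dispersion`,
#'   and list-column `unitary`.
#' @export
simulate_ensemble_agent <- function(cohort, n_unitary = 50, skill = 0.25,
                                    dispersion_coupling = 1, noise_sd = 0.15,
                                    seed = 1) {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (n_unitary < 2) stop_config("{.arg n_unitary} must be at least 2.")
  if (skill < 0 || skill > 1) stop_config("{.arg skill} must be in [0, 1].")
  if (dispersion_coupling < 0) stop_config("{.arg dispersion_coupling} must be >= 0.")
  withr::local_seed(substream_seed(seed, "ensemble"))

  horizons <- cohort$config$horizons
  long <- tidyr::pivot_longer(cohort$outcomes, -"record_id",
                              names_to = "horizon", names_prefix = "T_",
                              values_to = "y") %>%
    dplyr::mutate(horizon = as.integer(.data$horizon)) %>%
    dplyr::left_join(cohort$truth[c("record_id", "hardness")], by = "record_id")

  eta <- runif(nrow(long))
  w <- skill^(1 + dispersion_coupling * long$hardness)
  anchor <- w * long$y + (1 - w) * eta
  spread <- noise_sd * (1 + dispersion_coupling * long$hardness)
  unitary <- purrr::map2(anchor, spread, function(m, s) {
    pmin(pmax(m + rnorm(n_unitary, sd = s), 0), 1)
  })
  tibble::tibble(
    record_id = long$record_id, horizon = long$horizon,
    mean = vapply(unitary, mean, numeric(1)),
    dispersion = vapply(unitary, sd, numeric(1)),
    unitary = unitary
  )
}

#' Write a full set of synthetic fixture tables
#'
#' Generates a cohort, a rater panel and a simulated ensemble agent and
#' writes the three canonical CSV layouts (outcomes, ratings, machine
#' scores) plus the feature table. All files are synthetic stand-ins.
#'
#' @param dir Output directory (created if needed).
#' @param cohort_cfg,rater_cfg Generator configurations.
#' @param seed Master seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, cohort_cfg = cohort_config(),
                          rater_cfg = rater_config(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(cohort_cfg, seed = seed)
  ratings <- simulate_raters(cohort, rater_cfg, seed = seed)
  machine <- simulate_ensemble_agent(cohort, seed = seed)
  paths <- c(
    records = file.path(dir, "synthetic_records.csv"),
    outcomes = file.path(dir, "synthetic_outcomes.csv"),
    ratings = file.path(dir, "synthetic_ratings.csv"),
    scores = file.path(dir, "synthetic_rf_scores.csv")
  )
  readr::write_csv(cohort$records, paths[["records"]])
  write_outcomes(cohort$outcomes, paths[["outcomes"]])
  write_human_predictions(ratings, paths[["ratings"]])
  write_ensemble_predictions(
    machine[c("record_id", "horizon")] %>%
      dplyr::mutate(probability = machine$mean),
    paths[["scores"]])
  invisible(paths)
}
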