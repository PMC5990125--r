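suppressMessages(library(dplyr))

test_that("cohorts are reproducible and labels are always horizon-monotone", {
  a <- simulate_cohort(cohort_config(), seed = 11)
  b <- simulate_cohort(cohort_config(), seed = 11)
  expect_identical(a$records, b$records)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth, b$truth)

  for (s in 1:20) {
    co <- simulate_cohort(cohort_config(n_patients = 30, n_features = 2), seed = s)
    expect_true(all(co$outcomes$T_180 <= co$outcomes$T_360))
    expect_true(all(co$outcomes$T_360 <= co$outcomes$T_720))
    prev <- colMeans(co$outcomes[c("T_180", "T_360", "T_720")])
    expect_true(all(diff(prev) >= 0))
  }
})

test_that("an infinite hazard scale yields no transitions at any horizon", {
  co <- simulate_cohort(cohort_config(hazard_scale = Inf, n_patients = 20),
                        seed = 2)
  expect_true(all(co$outcomes[c("T_180", "T_360", "T_720")] == 0))
})

test_that("degenerate generator configurations are rejected", {
  expect_error(cohort_config(hazard_scale = 0), class = "mshybrid_config_error")
  expect_error(cohort_config(n_patients = 1), class = "mshybrid_config_error")
  expect_error(rater_config(skill = 1.5), class = "mshybrid_config_error")
  co <- small_cohort()
  expect_error(
    simulate_raters(co, rater_config(records_per_rater = nrow(co$records) + 1)),
    class = "mshybrid_config_error")
  expect_error(simulate_ensemble_agent(co, n_unitary = 1),
               class = "mshybrid_config_error")
})

test_that("rater coverage matches the assignment design by brute-force count", {
  co <- simulate_cohort(cohort_config(), seed = 5)
  cfg <- rater_config(n_raters = 42, records_per_rater = 50)
  ratings <- simulate_raters(co, cfg, seed = 5)
  # every rater scores exactly 50 records at each of 3 horizons
  per_rater <- ratings %>% count(rater_id, horizon)
  expect_true(all(per_rater$n == 50))
  # mean per-record coverage equals n_raters * records_per_rater / n_records
  cov <- ratings %>% filter(horizon == 180) %>% count(record_id)
  expect_equal(sum(cov$n) / nrow(co$records), 42 * 50 / nrow(co$records))
})

test_that("noiseless raters agree exactly on the discretized risk", {
  co <- small_cohort(seed = 7)
  cfg <- rater_config(n_raters = 8, records_per_rater = nrow(co$records),
                      skill = 1, dispersion_coupling = 0)
  ratings <- simulate_raters(co, cfg, seed = 7)
  spread <- ratings %>% count(record_id, horizon, score) %>%
    count(record_id, horizon)
  expect_true(all(spread$n == 1))  # all raters give the same score
  p <- tidyr::pivot_longer(co$truth[c("record_id", "p_180", "p_360", "p_720")],
                           -record_id, names_prefix = "p_",
                           names_to = "horizon", values_to = "p") %>%
    mutate(horizon = as.integer(horizon))
  joined <- ratings %>% distinct(record_id, horizon, score) %>%
    left_join(p, by = c("record_id", "horizon"))
  expect_equal(joined$score, pmin(floor(joined$p * 6), 5))
})

test_that("zero-skill raters are uninformative (per-rater AUC centred at 0.5)", {
  aucs <- c()
  for (s in 1:4) {
    co <- simulate_cohort(cohort_config(n_patients = 40, n_features = 2), seed = s)
    ratings <- simulate_raters(
      co, rater_config(n_raters = 60, records_per_rater = 100, skill = 0),
      seed = s)
    singles <- suppressMessages(singles_auc(ratings, co$outcomes, 360))
    aucs <- c(aucs, singles$per_rater$auc[singles$per_rater$eligible])
  }
  expect_gt(length(aucs), 200)
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.01)
})

test_that("ensemble agent forecasts are deterministic and collapse without noise", {
  co <- small_cohort(seed = 3)
  a <- simulate_ensemble_agent(co, n_unitary = 10, seed = 4)
  b <- simulate_ensemble_agent(co, n_unitary = 10, seed = 4)
  expect_identical(a, b)

  pure <- simulate_ensemble_agent(co, n_unitary = 10, skill = 0.5,
                                  dispersion_coupling = 0, noise_sd = 0, seed = 4)
  expect_true(all(pure$dispersion == 0))
  expect_true(all(vapply(pure$unitary, function(u) length(unique(u)) == 1,
                         logical(1))))
  expect_true(all(vapply(pure$unitary, length, integer(1)) == 10))
})

test_that("a maximally skilled ensemble separates the classes", {
  aucs <- vapply(1:3, function(s) {
    co <- simulate_cohort(cohort_config(n_patients = 40, n_features = 2), seed = s)
    ag <- simulate_ensemble_agent(co, n_unitary = 50, skill = 1, seed = s)
    m <- ag %>% filter(horizon == 360)
    auc <- roc_auc(m$mean, labels_for(co, m$record_id, 360))$auc
    auc
  }, numeric(1))
  expect_true(all(aucs > 0.99))
})

test_that("dispersion is coupled to misclassification when configured", {
  cors <- vapply(1:5, function(s) {
    co <- simulate_cohort(cohort_config(), seed = s)
    ag <- simulate_ensemble_agent(co, skill = 0.25, dispersion_coupling = 1,
                                  seed = s)
    m <- ag %>% filter(horizon == 360)
    y <- labels_for(co, m$record_id, 360)
    miss <- abs(m$mean - y)  # distance of the forecast from the truth
    cor(m$dispersion, miss, method = "spearman")
  }, numeric(1))
  expect_true(all(cors > 0))
})

test_that("make_fixtures writes the three canonical layouts consistently", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir, cohort_config(n_patients = 20, n_features = 2),
                         rater_config(n_raters = 6, records_per_rater = 20),
                         seed = 2)
  expect_true(all(file.exists(paths)))
  out <- read_outcomes(paths[["outcomes"]], quiet = TRUE)
  sc <- read_ensemble_predictions(paths[["scores"]], quiet = TRUE)
  ra <- read_human_predictions(paths[["ratings"]], quiet = TRUE)
  expect_equal(sort(unique(sc$record_id)), sort(out$record_id))
  expect_true(all(ra$record_id %in% out$record_id))
})
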