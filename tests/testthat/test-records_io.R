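suppressMessages(library(dplyr))

test_that("outcome tables round-trip through the deposited CSV layout", {
  cohort <- small_cohort(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcomes(cohort$outcomes, path)
  back <- read_outcomes(path, quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(cohort$outcomes))
})

test_that("outcome validation reports schema and label problems precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(record_id = 1:2, T_180 = c(0, 1), T_360 = c(0, 1)),
                   path)
  expect_error(read_outcomes(path, quiet = TRUE), class = "mshybrid_schema_error",
               regexp = "T_720")

  writeLines("", path)
  expect_error(read_outcomes(path, quiet = TRUE), class = "mshybrid_schema_error")

  readr::write_csv(tibble::tibble(record_id = 1:3, T_180 = c(0, 2, 0),
                                  T_360 = c(0, 1, 0), T_720 = c(0, 1, 1)), path)
  err <- expect_error(read_outcomes(path, quiet = TRUE),
                      class = "mshybrid_validation_error")
  expect_match(conditionMessage(err), "2")

  readr::write_csv(tibble::tibble(record_id = 1:3, T_180 = c(0, 1, 0),
                                  T_360 = c(0, 0, 0), T_720 = c(0, 1, 1)), path)
  expect_warning(read_outcomes(path, quiet = TRUE), regexp = "2")
  expect_error(read_outcomes(path, monotonicity = "error", quiet = TRUE),
               class = "mshybrid_validation_error")
})

test_that("a monotone three-record fixture reads without warnings", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(record_id = 1:3, T_180 = c(0, 0, 1),
                                  T_360 = c(0, 1, 1), T_720 = c(0, 1, 1)), path)
  expect_no_warning(out <- read_outcomes(path, quiet = TRUE))
  expect_equal(nrow(out), 3)
})

test_that("human ratings round-trip and reject invalid scores", {
  scores <- matrix(c(0, 5, 3, 2, 1, 4), nrow = 2)
  ratings <- ratings_from_matrix(scores)
  path <- withr::local_tempfile(fileext = ".csv")
  write_human_predictions(ratings, path)
  back <- read_human_predictions(path, quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(ratings))

  bad <- ratings
  bad$score[2] <- 7
  write_human_predictions(bad, path)
  expect_error(read_human_predictions(path, quiet = TRUE),
               class = "mshybrid_validation_error")

  dup <- dplyr::bind_rows(ratings, ratings[1, ])
  write_human_predictions(dup, path)
  expect_error(read_human_predictions(path, quiet = TRUE),
               class = "mshybrid_validation_error", regexp = "duplicate")
})

test_that("questionnaire block layout parses to the long rating collection", {
  # two questionnaires over 4 records; second rater shares records 3 and 4
  block <- rbind(
    c("Questionnaire", "Q1", "", ""),
    c("Clinical report N", "1", "2", "3"),
    c("Prediction @ 180", "0", "1", "2"),
    c("Prediction @ 360", "1", "2", "3"),
    c("Prediction @ 720", "2", "3", "4"),
    c("Questionnaire", "Q2", "", ""),
    c("Clinical report N", "3", "4", ""),
    c("Prediction @ 180", "5", "0", ""),
    c("Prediction @ 360", "5", "1", ""),
    c("Prediction @ 720", "5", "2", "")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(block, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  ratings <- read_human_predictions(path, quiet = TRUE)
  expect_equal(length(unique(ratings$rater_id)), 2)
  expect_equal(nrow(ratings), (3 + 2) * 3)
  # brute-force scan: record 3 appears in both questionnaires, so exactly
  # 2 ratings per horizon; records 1 and 4 get exactly 1
  per <- table(ratings$record_id[ratings$horizon == 360])
  expect_equal(unname(per[c("1", "3", "4")]), c(1, 2, 1), ignore_attr = TRUE)
  expect_equal(ratings$score[ratings$rater_id == "Q1" & ratings$horizon == 180],
               c(0, 1, 2))
})

test_that("ensemble score tables round-trip and validate probabilities", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(record_id = 1, Score_180 = 0,
                                  Score_360 = 0.5, Score_720 = 1), path)
  one <- read_ensemble_predictions(path, quiet = TRUE)
  expect_equal(nrow(one), 3)
  expect_equal(one$probability, c(0, 0.5, 1))

  withr::with_seed(9, {
    rnd <- tidyr::expand_grid(record_id = 1:20, horizon = c(180L, 360L, 720L))
    rnd$probability <- runif(nrow(rnd))
  })
  write_ensemble_predictions(rnd, path)
  back <- read_ensemble_predictions(path, quiet = TRUE)
  expect_equal(as.data.frame(dplyr::arrange(back, record_id, horizon)),
               as.data.frame(dplyr::arrange(rnd, record_id, horizon)))

  readr::write_csv(tibble::tibble(record_id = 7, Score_180 = 1.2,
                                  Score_360 = 0.5, Score_720 = 1), path)
  expect_error(read_ensemble_predictions(path, quiet = TRUE),
               class = "mshybrid_validation_error", regexp = "7")
})

test_that("results tables write one agent row with horizon columns and round-trip", {
  res <- tibble::tibble(
    agent = rep(c("Random Forest", "Group"), each = 3),
    horizon = rep(c(180L, 360L, 720L), 2),
    auc = c(0.710, 0.670, 0.679, 0.703, 0.667, 0.666),
    lower = auc - 0.05, upper = auc + 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(res, path)
  wide <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(wide), 2)
  expect_true(all(c("auc_180", "auc_360", "auc_720") %in% names(wide)))
  back <- read_results_table(path)
  expect_equal(as.data.frame(back[c("agent", "horizon", "auc", "lower", "upper")]),
               as.data.frame(res))
  expect_error(write_results_table(res[0, ], path),
               class = "mshybrid_validation_error")
})
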