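suppressMessages(library(dplyr))

test_that("concordance equals the sample standard deviation of unitary predictions", {
  expect_equal(concordance(c(0.4, 0.4, 0.4)), 0)
  expect_equal(concordance(c(0, 1)), sqrt(0.5), tolerance = 1e-12)
  expect_equal(round(concordance(c(0, 1)), 4), 0.7071)
  withr::with_seed(5, {
    for (i in 1:10) {
      u <- runif(sample(2:30, 1))
      expect_equal(concordance(u), two_pass_sd(u), tolerance = 1e-12)
    }
  })
  expect_error(concordance(0.5), class = "mshybrid_undefined_concordance")
  # list input vectorizes per record
  expect_equal(concordance(list(c(0, 1), c(0.2, 0.2))), c(sqrt(0.5), 0))
})

test_that("concordance ranks normalize to [0, 1] with the stated conventions", {
  expect_equal(concordance_ranks(c(0.0, 0.1, 0.2)), c(1, 0.5, 0))
  expect_warning(r <- concordance_ranks(rep(0.3, 4)), "equal")
  expect_equal(r, rep(0.5, 4))
  withr::with_seed(8, {
    d <- runif(100)
    expect_equal(concordance_ranks(d), sort_rank_oracle(d))
  })
  # max 1, min 0 whenever dispersions are distinct; non-increasing in dispersion
  withr::with_seed(9, d2 <- sample(seq(0, 1, by = 0.01), 40))
  r2 <- concordance_ranks(d2)
  expect_equal(max(r2), 1)
  expect_equal(min(r2), 0)
  expect_true(all(diff(r2[order(d2)]) <= 0))
  # ties share the average rank
  expect_equal(concordance_ranks(c(0.1, 0.1, 0.5)), c(0.75, 0.75, 0))
})

test_that("the weighted mode reduces to single agents at extreme ranks", {
  # two records force ranks (1, 0) for human and (0, 1) for machine
  human <- tibble::tibble(record_id = 1:2, mean = c(0.8, 0.3),
                          dispersion = c(0.1, 0.2))
  machine <- tibble::tibble(record_id = 1:2, mean = c(0.6, 0.9),
                            dispersion = c(0.2, 0.1))
  hs <- hybrid_score(human, machine, mode = "weighted")
  expect_equal(hs$rank_human, c(1, 0))
  expect_equal(hs$rank_machine, c(0, 1))
  expect_equal(hs$score, c(0.8, 0.9))  # each agent alone where its rank is 1
})

test_that("equal ranks average the two forecast means", {
  # identical dispersion patterns give both agents the same ranks
  human <- tibble::tibble(record_id = 1:3, mean = c(0.8, 0.5, 0.2),
                          dispersion = c(0.1, 0.2, 0.3))
  machine <- tibble::tibble(record_id = 1:3, mean = c(0.6, 0.1, 0.4),
                            dispersion = c(0.1, 0.2, 0.3))
  hs <- hybrid_score(human, machine, mode = "weighted")
  expect_equal(hs$score[1], 0.7)  # ranks 1, 1 -> plain average of 0.8 and 0.6
  expect_equal(hs$score[3], 0.3)  # both ranks 0 -> fallback to plain mean
})

test_that("the paper-literal sum of squared ranks is direction-free and bounded", {
  withr::with_seed(3, {
    human <- tibble::tibble(record_id = 1:20, mean = runif(20),
                            dispersion = runif(20))
    machine <- tibble::tibble(record_id = 1:20, mean = runif(20),
                              dispersion = runif(20))
  })
  hs <- hybrid_score(human, machine, mode = "sum_sq_ranks")
  expect_equal(hs$score, hs$rank_human^2 + hs$rank_machine^2)
  expect_true(all(hs$score >= 0 & hs$score <= 2))
  # the score ignores the forecast means entirely
  hs2 <- hybrid_score(dplyr::mutate(human, mean = 1 - mean), machine,
                      mode = "sum_sq_ranks")
  expect_equal(hs2$score, hs$score)
})

test_that("weighted scores are bracketed by the two forecast means", {
  withr::with_seed(21, {
    for (i in 1:5) {
      n <- 30
      human <- tibble::tibble(record_id = 1:n, mean = runif(n),
                              dispersion = runif(n))
      machine <- tibble::tibble(record_id = 1:n, mean = runif(n),
                                dispersion = runif(n))
      for (mode in c("weighted", "linear_ranks", "unranked")) {
        hs <- hybrid_score(human, machine, mode = mode)
        expect_true(all(hs$score >= pmin(hs$mean_human, hs$mean_machine) - 1e-12))
        expect_true(all(hs$score <= pmax(hs$mean_human, hs$mean_machine) + 1e-12))
      }
    }
  })
})

test_that("identical agents make the hybrid equal to either agent", {
  withr::with_seed(14, {
    agent <- tibble::tibble(record_id = 1:50, mean = runif(50),
                            dispersion = runif(50))
    labels <- rbinom(50, 1, 0.4)
  })
  hs <- hybrid_score(agent, agent, mode = "weighted")
  expect_equal(hs$score, agent$mean)
  expect_equal(roc_auc(hs$score, labels)$auc, roc_auc(agent$mean, labels)$auc)
})

test_that("a zero-dispersion agent takes all the weight in the unranked mode", {
  human <- tibble::tibble(record_id = 1:3, mean = c(0.9, 0.2, 0.6),
                          dispersion = c(0, 0.1, 0.3))
  machine <- tibble::tibble(record_id = 1:3, mean = c(0.1, 0.8, 0.6),
                            dispersion = c(0.2, 0, 0))
  hs <- hybrid_score(human, machine, mode = "unranked")
  expect_equal(hs$score[1], 0.9)  # human is perfectly concordant
  expect_equal(hs$score[2], 0.8)  # machine is
  expect_equal(hs$score[3], 0.6)
})

test_that("mismatched record sets are dropped by default and fatal when strict", {
  human <- tibble::tibble(record_id = 1:4, mean = runif(4), dispersion = runif(4))
  machine <- tibble::tibble(record_id = 3:6, mean = runif(4), dispersion = runif(4))
  expect_message(hs <- hybrid_score(human, machine), "4 record")
  expect_equal(hs$record_id, 3:4)
  expect_error(hybrid_score(human, machine, strict = TRUE),
               class = "mshybrid_key_error")
})

test_that("ranks are computed within each horizon separately", {
  human <- tibble::tibble(record_id = rep(1:3, 2),
                          horizon = rep(c(180L, 360L), each = 3),
                          mean = runif(6), dispersion = c(1, 2, 3, 3, 2, 1))
  machine <- human
  hs <- hybrid_score(human, machine)
  expect_equal(hs$rank_human[hs$horizon == 180], c(1, 0.5, 0))
  expect_equal(hs$rank_human[hs$horizon == 360], c(0, 0.5, 1))
})
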