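# End-to-end orchestration: crowd aggregation, ensemble scoring, hybrid
# combination and bootstrap evaluation for every horizon, from deposited
# tables or from a synthetic cohort, to an agent-by-horizon report.

#' Configure a full experiment run
#'
#' @param mode `"synthetic"` (generate a cohort, raters and a machine
#'   agent) or `"deposited"` (read the three canonical tables).
#' @param outcomes_path,ratings_path,scores_path File paths, required in
#'   deposited mode.
#' @param cohort,raters Generator configurations for synthetic mode.
#' @param machine Machine-agent specification for synthetic mode: a list
#'   with `method = "simulated"` (draws a dispersion-coupled ensemble via
#'   [simulate_ensemble_agent()]; fields `n_unitary`, `skill`,
#'   `dispersion_coupling`, `noise_sd`) or `method = "loo"` (full
#'   leave-one-patient-out retraining via [fit_predict_loo()]; fields
#'   `n_sets`, `num_trees`).
#' @param horizons Horizons to evaluate, days.
#' @param hybrid_mode Combination mode for [hybrid_score()].
#' @param n_boot Bootstrap replicates per agent and horizon.
#' @param level Confidence level.
#' @param pairs_draws Random 2-of-k selections averaged in the Pairs
#'   condition.
#' @param seed Master seed; every stage derives a named substream from it.
#' @param output_dir If non-`NULL`, results CSV, evaluation JSON and a run
#'   manifest are written there.
#' @return A `run_config` list.
#' @export
experiment_config <- function(mode = c("synthetic", "deposited"),
                              outcomes_path = NULL, ratings_path = NULL,
                              scores_path = NULL,
                              cohort = cohort_config(),
                              raters = rater_config(),
                              machine = list(method = "simulated",
                                             n_unitary = 50, skill = 0.25,
                                             dispersion_coupling = 1,
                                             noise_sd = 0.15),
                              horizons = HORIZONS,
                              hybrid_mode = "weighted",
                              n_boot = 1000, level = 0.95, pairs_draws = 100,
                              seed = 1, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "deposited") {
    paths <- c(outcomes = outcomes_path, ratings = ratings_path,
               scores = scores_path)
    if (length(paths) < 3) {
      stop_config("Deposited mode needs {.arg outcomes_path}, {.arg ratings_path} and {.arg scores_path}.")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop_config("{length(missing)} input file{?s} not found: {.path {missing}}.")
    }
  }
  structure(list(
    mode = mode, outcomes_path = outcomes_path, ratings_path = ratings_path,
    scores_path = scores_path, cohort = cohort, raters = raters,
    machine = machine, horizons = as.integer(horizons),
    hybrid_mode = hybrid_mode, n_boot = n_boot, level = level,
    pairs_draws = pairs_draws, seed = seed, output_dir = output_dir
  ), class = "run_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      cli::cli_abort("Stage {.val {stage}} failed: {conditionMessage(e)}",
                     class = "mshybrid_stage_error", parent = e)
    })
}

# Group scores -> a human forecast table for the hybrid stage. Dispersion
# uses all available ratings per record; records with a single rating have
# no within-record dispersion and are assigned the panel's maximum (treated
# as least consistent).
human_forecast_from_group <- function(group) {
  disp <- group$scores$dispersion
  if (all(is.na(disp))) disp[] <- 0 else disp[is.na(disp)] <- max(disp, na.rm = TRUE)
  tibble::tibble(record_id = group$scores$record_id,
                 mean = group$scores$score, dispersion = disp)
}

quiet_rank_ties <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("dispersions equal", conditionMessage(w))) {
      rlang::cnd_muffle(w)
    }
  })
}

#' Run the full human/machine/hybrid experiment
#'
#' Executes, for every configured horizon: crowd aggregation of the human
#' ratings (Singles, Pairs, Group), machine ensemble scoring (deposited
#' probabilities, simulated agent, or full leave-one-patient-out
#' retraining), concordance-ranked hybrid combination over the rated
#' records, and tie-aware AUC evaluation with percentile-bootstrap
#' confidence intervals, plus paired bootstrap comparisons of the hybrid
#' against the Group and machine agents. The run is deterministic for a
#' fixed configuration.
#'
#' In deposited mode the machine agent's unitary predictions are not
#' available, so its per-record dispersion is unknown; the hybrid stage
#' then falls back to a uniform machine concordance rank of 0.5 (flagged
#' in the manifest), making the hybrid values mode-dependent.
#'
#' @param config A [experiment_config()].
#' @return An object of class `hybrid_experiment` with elements `results`
#'   (tibble: `agent`, `horizon`, `auc`, `lower`, `upper`, `q1`, `median`,
#'   `q3`, `sd`), `details` (per-horizon objects), `comparisons`
#'   (paired AUC differences), `manifest`, `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  data <- with_stage("load", {
    if (config$mode == "deposited") {
      outcomes <- read_outcomes(config$outcomes_path, quiet = TRUE)
      ratings <- read_human_predictions(config$ratings_path, quiet = TRUE)
      scores <- read_ensemble_predictions(config$scores_path, quiet = TRUE)
      machine <- scores %>%
        dplyr::transmute(.data$record_id, .data$horizon,
                         mean = .data$probability, dispersion = NA_real_)
      list(outcomes = outcomes, ratings = ratings, machine = machine,
           patient_id = NULL)
    } else {
      cohort <- simulate_cohort(config$cohort, seed = seed)
      ratings <- simulate_raters(cohort, config$raters, seed = seed)
      machine <- if (identical(config$machine$method, "loo")) {
        purrr::map_dfr(config$horizons, function(h) {
          fit_predict_loo(cohort$records, cohort$outcomes, h,
                          base_learner = rf_learner(
                            num_trees = config$machine$num_trees %||% 100),
                          n_sets = config$machine$n_sets %||% 50, seed = seed)
        })
      } else {
        simulate_ensemble_agent(
          cohort, n_unitary = config$machine$n_unitary %||% 50,
          skill = config$machine$skill %||% 0.25,
          dispersion_coupling = config$machine$dispersion_coupling %||% 1,
          noise_sd = config$machine$noise_sd %||% 0.15, seed = seed)
      }
      list(outcomes = cohort$outcomes, ratings = ratings, machine = machine,
           patient_id = cohort$records$patient_id, cohort = cohort)
    }
  })

  machine_rank_fallback <- all(is.na(data$machine$dispersion))
  rows <- list()
  details <- list()
  comparisons <- list()

  for (h in config$horizons) {
    hchr <- as.character(h)
    lab_col <- paste0("T_", h)

    singles <- with_stage("crowd-singles", singles_auc(data$ratings, data$outcomes, h))
    pairs <- with_stage("crowd-pairs",
                        pairs_auc(data$ratings, data$outcomes, h,
                                  n_draws = config$pairs_draws, seed = seed))
    group <- with_stage("crowd-group", group_auc(data$ratings, data$outcomes, h))

    mach_h <- data$machine %>% dplyr::filter(.data$horizon == h)
    mach_labels <- data$outcomes[[lab_col]][match(mach_h$record_id,
                                                  data$outcomes$record_id)]
    mach_boot <- with_stage("evaluate-machine",
                            bootstrap_auc(mach_h$mean, mach_labels,
                                          n_boot = config$n_boot,
                                          level = config$level, seed = seed))
    group_boot <- with_stage("evaluate-group",
                             bootstrap_auc(group$scores$score, group$scores$label,
                                           n_boot = config$n_boot,
                                           level = config$level, seed = seed))

    hybrid <- with_stage("hybrid", {
      human_fc <- human_forecast_from_group(group)
      mach_fc <- mach_h[c("record_id", "mean", "dispersion")]
      if (machine_rank_fallback) mach_fc$dispersion <- 0
      quiet_rank_ties(
        hybrid_score(human_fc, mach_fc, mode = config$hybrid_mode))
    })
    hyb_labels <- data$outcomes[[lab_col]][match(hybrid$record_id,
                                                 data$outcomes$record_id)]
    hyb_boot <- with_stage("evaluate-hybrid",
                           bootstrap_auc(hybrid$score, hyb_labels,
                                         n_boot = config$n_boot,
                                         level = config$level, seed = seed))

    shared <- hybrid$record_id
    comparisons[[hchr]] <- with_stage("compare", list(
      hybrid_vs_group = auc_difference(
        setNames(hybrid$score, shared),
        setNames(group$scores$score, group$scores$record_id)[as.character(shared)],
        hyb_labels, n_boot = config$n_boot, level = config$level, seed = seed),
      hybrid_vs_machine = auc_difference(
        setNames(hybrid$score, shared),
        setNames(mach_h$mean, mach_h$record_id)[as.character(shared)],
        hyb_labels, n_boot = config$n_boot, level = config$level, seed = seed)
    ))

    boot_row <- function(agent, boot, sd = NA_real_) {
      tibble::tibble(agent = agent, horizon = h, auc = boot$point_auc,
                     lower = boot$ci[1], upper = boot$ci[2],
                     q1 = boot$quartiles[1], median = boot$quartiles[2],
                     q3 = boot$quartiles[3], sd = sd)
    }
    rows[[hchr]] <- dplyr::bind_rows(
      boot_row("Random Forest", mach_boot),
      tibble::tibble(agent = "Singles", horizon = h, auc = singles$mean,
                     lower = NA_real_, upper = NA_real_, q1 = NA_real_,
                     median = NA_real_, q3 = NA_real_, sd = singles$sd),
      tibble::tibble(agent = "Pairs", horizon = h, auc = pairs$auc,
                     lower = NA_real_, upper = NA_real_, q1 = NA_real_,
                     median = NA_real_, q3 = NA_real_, sd = sd(pairs$draws)),
      boot_row("Group", group_boot),
      boot_row("Hybrid", hyb_boot)
    )
    details[[hchr]] <- list(singles = singles, pairs = pairs, group = group,
                            machine = mach_boot, group_boot = group_boot,
                            hybrid = hybrid, hybrid_boot = hyb_boot)
  }

  results <- dplyr::bind_rows(rows)
  manifest <- list(
    package = "mshybrid", version = as.character(packageVersion("mshybrid")),
    r_version = as.character(getRversion()),
    mode = config$mode, seed = seed, horizons = config$horizons,
    hybrid_mode = config$hybrid_mode, n_boot = config$n_boot,
    level = config$level, pairs_draws = config$pairs_draws,
    machine_rank_fallback = machine_rank_fallback,
    machine = config$machine,
    cohort = if (config$mode == "synthetic") unclass(config$cohort),
    raters = if (config$mode == "synthetic") unclass(config$raters)
  )

  out <- structure(list(results = results, details = details,
                        comparisons = comparisons, manifest = manifest,
                        config = config),
                   class = "hybrid_experiment")
  if (!is.null(config$output_dir)) {
    with_stage("write", write_experiment(out, config$output_dir))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch({
    p1 <- file.path(dir, "results.csv")
    write_results_table(experiment$results, p1)
    written <- c(written, p1)
    p2 <- file.path(dir, "evaluation.json")
    eval_payload <- purrr::imap(experiment$details, function(d, h) {
      list(
        machine = boot_summary_json(d$machine),
        group = boot_summary_json(d$group_boot),
        hybrid = boot_summary_json(d$hybrid_boot),
        singles = list(mean = d$singles$mean, sd = d$singles$sd,
                       n_eligible = d$singles$n_eligible),
        pairs = list(auc = d$pairs$auc, n_draws = d$pairs$n_draws),
        hybrid_vs_group = diff_json(experiment$comparisons[[h]]$hybrid_vs_group),
        hybrid_vs_machine = diff_json(experiment$comparisons[[h]]$hybrid_vs_machine)
      )
    })
    jsonlite::write_json(eval_payload, p2, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, p2)
    p3 <- file.path(dir, "manifest.json")
    jsonlite::write_json(experiment$manifest, p3, auto_unbox = TRUE,
                         digits = NA, null = "null")
    written <- c(written, p3)
    p4 <- file.path(dir, "bootstrap_boxes.csv")
    readr::write_csv(box_summary(experiment), p4)
    invisible(c(written, p4))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

boot_summary_json <- function(b) {
  list(point_auc = b$point_auc, ci = b$ci, quartiles = b$quartiles,
       range = b$range, level = b$level, n_boot = b$n_boot,
       n_redrawn = b$n_redrawn)
}

diff_json <- function(d) {
  list(delta = d$delta, ci = d$ci, p_value = d$p_value,
       significant = d$significant)
}

# Box-plot-ready summary (boxes = quartiles, whiskers = full range) of the
# bootstrap AUC distributions for the bootstrapped agents.
box_summary <- function(experiment) {
  purrr::imap_dfr(experiment$details, function(d, h) {
    one <- function(agent, b) {
      tibble::tibble(agent = agent, horizon = as.integer(h),
                     q1 = b$quartiles[1], median = b$quartiles[2],
                     q3 = b$quartiles[3], min = b$range[1], max = b$range[2])
    }
    dplyr::bind_rows(one("Random Forest", d$machine), one("Group", d$group_boot),
                     one("Hybrid", d$hybrid_boot))
  })
}

#' @export
print.hybrid_experiment <- function(x, ...) {
  cli::cli_text("<hybrid_experiment> mode = {x$manifest$mode}, seed = {x$manifest$seed}")
  wide <- x$results %>%
    dplyr::mutate(cell = ifelse(
      .data$agent == "Singles",
      sprintf("%.2f ± %.2f", .data$auc, .data$sd),
      sprintf("%.3f", .data$auc))) %>%
    tidyr::pivot_wider(id_cols = "agent", names_from = "horizon",
                       values_from = "cell", names_glue = "{horizon} d")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Recompute the headline checks from user-supplied deposited tables
#'
#' Given a directory containing CSV conversions of the three deposited
#' tables (`TrueOutcomes.csv`, `Student_Predictions.csv`,
#' `RF_Predictions.csv`; XLSX accepted with the same stems), recomputes the
#' quantities that identify the dataset and the single-agent results: the
#' record count and per-horizon positive counts, the machine AUC per
#' horizon, and the Singles, Pairs and Group AUCs. The hybrid values
#' cannot be recomputed from the deposited tables alone, because the
#' machine agent's unitary predictions were not deposited.
#'
#' @param dir Directory holding the three tables.
#' @param pairs_draws,seed Passed to [pairs_auc()].
#' @return A list with `counts` (named integer vector), and tibbles
#'   `machine_auc`, `crowd` (`condition`, `horizon`, `auc`, `sd`).
#' @export
reproduce_deposited_results <- function(dir, pairs_draws = 100, seed = 1) {
  find <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem, "\\.(csv|xlsx)$"),
                       ignore.case = TRUE, full.names = TRUE)
    if (length(hits) == 0) {
      stop_config("No {stem}.csv or {stem}.xlsx in {.path {dir}}.")
    }
    hits[[1]]
  }
  outcomes <- read_outcomes(find("TrueOutcomes"), quiet = TRUE)
  ratings <- read_human_predictions(find("Student_Predictions"), quiet = TRUE)
  scores <- read_ensemble_predictions(find("RF_Predictions"), quiet = TRUE)

  counts <- c(n_records = nrow(outcomes),
              setNames(colSums(outcomes[horizon_label_cols()]),
                       paste0("n_pos_", HORIZONS)))
  machine_auc <- scores %>%
    dplyr::group_by(.data$horizon) %>%
    dplyr::summarise(auc = {
      y <- outcomes[[paste0("T_", .data$horizon[1])]][
        match(.data$record_id, outcomes$record_id)]
      roc_auc(.data$probability, y)$auc
    }, .groups = "drop")
  crowd <- purrr::map_dfr(HORIZONS, function(h) {
    s <- singles_auc(ratings, outcomes, h)
    p <- pairs_auc(ratings, outcomes, h, n_draws = pairs_draws, seed = seed)
    g <- group_auc(ratings, outcomes, h)
    tibble::tibble(condition = c("singles", "pairs", "group"), horizon = h,
                   auc = c(s$mean, p$auc, g$auc),
                   sd = c(s$sd, sd(p$draws), NA_real_))
  })
  list(counts = counts, machine_auc = machine_auc, crowd = crowd)
}
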