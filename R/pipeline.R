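#' Published summary counts of the motivating trial
#'
#' The individual-level trial data are not public, but the published
#' summary tables are, and every comparison statistic in this package
#' can be recomputed from them: the head-to-head counts achieved by the
#' ensemble-identified and scale-identified sets of 49 key influencers
#' (kits distributed, positive alters, first-time-tester alters, each
#' with its total), the per-fold simulated intervention efficiencies of
#' the two strategies, and the headline marginals (309 indexes, 269
#' alters, 60 key distributors).
#'
#' @return A nested list of the published counts.
#' @export
trial_reference_counts <- function() {
  list(
    n_indexes = 309L, n_alters = 269L,
    n_key_distributors = 60L, n_key_promoters = 73L, n_key_detectors = 23L,
    comparison = list(
      kits = c(ml = 146L, baseline = 97L, total = 269L),
      positive = c(ml = 11L, baseline = 8L, total = 25L),
      first_time = c(ml = 33L, baseline = 19L, total = 103L)
    ),
    efficiency = list(
      ml = c(72.7, 68.5, 65.0, 75.0, 79.6),
      baseline = c(64.6, 58.0, 51.3, 36.8, 61.9)
    )
  )
}

#' Recompute the published comparison arithmetic
#'
#' A self-check that the package's comparison statistics, applied to the
#' published summary counts, reproduce the published derived values:
#' increased percentages with the shared-total denominator, Wald
#' difference-of-proportions confidence intervals, the per-fold
#' efficiency averages with their difference, the fold-difference
#' confidence interval, and the headline proportions.
#'
#' @param counts Published counts, by default [trial_reference_counts()].
#' @return A list of the recomputed quantities.
#' @examples
#' selftest_printed_arithmetic()$increased_percentage
#' @export
selftest_printed_arithmetic <- function(counts = trial_reference_counts()) {
  cmp <- counts$comparison
  inc <- vapply(cmp, function(x) {
    increased_percentage(x[["ml"]], x[["baseline"]], x[["total"]])
  }, numeric(1))
  cis <- lapply(cmp, function(x) {
    wald_diff_ci(x[["ml"]], x[["baseline"]], x[["total"]])
  })
  eff <- counts$efficiency
  avg_ml <- round(mean(eff$ml), 1)
  avg_base <- round(mean(eff$baseline), 1)
  diffs <- eff$ml - eff$baseline
  list(
    increased_percentage = inc,
    wald_ci = cis,
    efficiency_average = c(ml = avg_ml, baseline = avg_base),
    efficiency_difference = round(avg_ml - avg_base, 1),
    efficiency_diff_ci = fold_diff_ci(diffs),
    distributor_prevalence_pct =
      round(100 * counts$n_key_distributors / counts$n_indexes, 1),
    ml_kit_share_pct =
      round(100 * cmp$kits[["ml"]] / cmp$kits[["total"]])
  )
}

#' Configuration of a full synthetic study
#'
#' @param generator A [generator_config()].
#' @param ensemble An [ensemble_config()].
#' @param simulation A [simulation_config()].
#' @param fold_seed Seed of the 5-fold plan.
#' @param n_replicates Simulation repeats per fold and strategy.
#' @param output_dir Optional directory; when given, [run_study()]
#'   persists the dataset, predictions, metrics, network edge lists,
#'   transfer logs and the report there.
#' @return Object of class `study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         ensemble = ensemble_config(),
                         simulation = simulation_config(),
                         fold_seed = 1L, n_replicates = 20L,
                         output_dir = NULL) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(ensemble, "ensemble_config"),
            inherits(simulation, "simulation_config"))
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop_config("n_replicates", "must be >= 1")
  }
  structure(list(generator = generator, ensemble = ensemble,
                 simulation = simulation, fold_seed = as.integer(fold_seed),
                 n_replicates = as.integer(n_replicates),
                 output_dir = output_dir),
            class = "study_config")
}

#' Run the complete identification study on synthetic data
#'
#' Orchestrates the whole pipeline deterministically from the configured
#' seeds: generate a synthetic trial dataset; cross-validate the four
#' base classifiers, the soft-voting ensemble and the two scale cutoffs
#' for all three influencer rules; compare the out-of-fold ensemble
#' flags against scale cutoff A on kit/first-time/positive counts
#' (increased percentages with Wald intervals); and run the
#' kit-diffusion simulation on each test fold to compare intervention
#' efficiency of the two seeding strategies.
#'
#' @param config A [study_config()].
#' @param rules Influencer rules to evaluate (default all three).
#' @return Object of class `study_report`: `dataset`, `metrics` (per
#'   rule), `count_comparison`, `efficiency_comparison`, `selftest`
#'   (published-arithmetic check), and the `config`.
#' @export
run_study <- function(config = study_config(),
                      rules = c("distributor", "promoter", "detector")) {
  rules <- match.arg(rules, several.ok = TRUE)
  dataset <- generate_trial(config$generator)
  cv <- lapply(setNames(rules, rules), function(r) {
    cross_validate(dataset, r, config = config$ensemble,
                   fold_seed = config$fold_seed)
  })

  # Table-2 analogue: out-of-fold ensemble ranking for the distributor
  # rule vs scale cutoff A, headcount-matched (the published comparison
  # contrasts equally sized influencer sets, so neither strategy gains
  # by merely flagging more people)
  lead_rule <- rules[1]
  pred <- cv[[lead_rule]]$predictions
  ens <- pred[pred$method == "ensemble", ]
  ens <- ens[match(dataset$indexes$index_id, ens$index_id), ]
  scores <- score_scale(dataset$indexes[, paste0("scale_", 1:6)])
  cutoffs <- find_cutoffs(scores)
  base_flags <- baseline_classify(scores, cutoffs, "A")
  n_match <- sum(base_flags)
  ml_rank <- order(-ens$probability, seq_along(ens$probability))
  ml_flags <- integer(nrow(dataset$indexes))
  ml_flags[ml_rank[seq_len(n_match)]] <- 1L
  idx <- dataset$indexes
  count_of <- function(flags, col) sum(idx[[col]][flags == 1L])
  comparison <- lapply(list(
    kits = "n_alters", first_time = "n_first_time_alters",
    positive = "n_positive_alters"
  ), function(col) {
    n_ml <- count_of(ml_flags, col)
    n_base <- count_of(base_flags, col)
    n_total <- sum(idx[[col]])
    list(ml = n_ml, baseline = n_base, total = n_total,
         increased_percentage = if (n_total > 0) {
           increased_percentage(n_ml, n_base, n_total)
         } else NA_real_,
         wald_ci = if (n_total > 0) {
           wald_diff_ci(n_ml, n_base, n_total)
         } else NULL)
  })

  # Table-3 analogue: per-fold diffusion efficiency, ML vs cutoff A seeds
  efficiency <- compare_strategies(dataset, cv[[lead_rule]]$folds,
                                   ml_flags, base_flags,
                                   config$simulation, config$n_replicates)

  report <- structure(
    list(dataset = dataset,
         metrics = lapply(cv, function(x) list(average = x$average,
                                               per_fold = x$per_fold)),
         selected_predictors = lapply(cv, `[[`, "selected_per_fold"),
         predictions = do.call(rbind, lapply(cv, `[[`, "predictions")),
         cutoffs = cutoffs,
         comparison_flags = data.frame(index_id = idx$index_id,
                                       ml = ml_flags,
                                       baseline = base_flags,
                                       stringsAsFactors = FALSE),
         count_comparison = comparison,
         efficiency_comparison = efficiency,
         selftest = selftest_printed_arithmetic(),
         config = config),
    class = "study_report"
  )
  if (!is.null(config$output_dir)) write_study_outputs(report)
  report
}

write_study_outputs <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(report$dataset, dir)
  write.csv(report$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  metrics <- do.call(rbind, lapply(report$metrics, `[[`, "average"))
  write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(report$efficiency_comparison$per_fold,
            file.path(dir, "efficiency.csv"), row.names = FALSE)
  json <- list(
    manifest = list(
      weights = report$config$ensemble$weights,
      decision_threshold = report$config$ensemble$decision_threshold,
      seeds = list(generator = report$config$generator$seed,
                   ensemble = report$config$ensemble$seed,
                   simulation = report$config$simulation$seed,
                   folds = report$config$fold_seed),
      selected_predictors = report$selected_predictors
    ),
    count_comparison = report$count_comparison,
    efficiency = list(
      per_fold = report$efficiency_comparison$per_fold,
      average = as.list(report$efficiency_comparison$average),
      diff_ci = as.list(report$efficiency_comparison$diff_ci)
    ),
    selftest = report$selftest,
    cutoffs = unclass(report$cutoffs)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (r in names(x$metrics)) {
    cat(sprintf("-- rule '%s' (5-fold averages) --\n", r))
    print(x$metrics[[r]]$average, digits = 3)
  }
  cc <- x$count_comparison
  cat(sprintf(
    "kits: ML %d vs baseline %d of %d (increase %.1f%%)\n",
    cc$kits$ml, cc$kits$baseline, cc$kits$total,
    cc$kits$increased_percentage))
  print(x$efficiency_comparison)
  invisible(x)
}
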