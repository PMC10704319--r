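#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary vectors; the positive class
#'   (1) is the key influencer.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- coerce_binary(y_true)
  y_pred <- coerce_binary(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("validation error: y_true and y_pred lengths differ", call. = FALSE)
  }
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' F1 is the harmonic mean of precision and recall. Zero-denominator
#' conventions: precision, recall and F1 are 0 when undefined.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0L) stop("validation error: no observations", call. = FALSE)
  precision <- if (counts$tp + counts$fp > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else 0
  recall <- if (counts$tp + counts$fn > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(accuracy = (counts$tp + counts$tn) / n, precision = precision,
    recall = recall, f1 = f1)
}

#' Stratified k-fold plan
#'
#' Indices are shuffled within each class and dealt cyclically to folds,
#' so fold sizes differ by at most one and each fold keeps roughly the
#' class prevalence (required at the ~7% positive prevalence of the
#' key-detector rule).
#'
#' @param y Binary labels.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return List of `k` integer vectors of test indices partitioning
#'   `seq_along(y)`.
#' @export
fold_plan <- function(y, k = 5L, seed = 1L) {
  y <- coerce_binary(y)
  n <- length(y)
  if (n < k) stop("validation error: fewer observations than folds",
                  call. = FALSE)
  ord <- withr::with_seed(child_seed(seed, 21L), {
    c(sample(which(y == 1)), sample(which(y == 0)))
  })
  assignment <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(j) sort(ord[assignment == j]))
}

#' Cross-validated evaluation of identification methods
#'
#' Runs stratified 5-fold cross-validation of any subset of the seven
#' methods: the four base classifier families, the soft-voting
#' `ensemble`, and the leadership-scale baselines `cutoffA` / `cutoffB`.
#' For the machine-learning methods the full two-pass system (importance
#' voting and refit on selected predictors) is fitted inside each
#' training fold; the single-family results reuse that fold's refitted
#' member model. The scale cutoffs are computed once from the full
#' sample's scores (as a field programme would set them) and applied to
#' the same test folds, so all methods are scored on identical data.
#'
#' @param dataset A labeled `trial_dataset`.
#' @param rule Influencer rule to predict.
#' @param methods Character vector among `"LR"`, `"SVM"`, `"DT"`,
#'   `"RF"`, `"ensemble"`, `"cutoffA"`, `"cutoffB"`.
#' @param config An [ensemble_config()].
#' @param k Number of folds.
#' @param fold_seed Seed of the fold shuffle.
#' @return Object of class `cv_result`: list with `per_fold` (metrics
#'   per fold and method), `average` (unweighted fold means),
#'   `predictions` (out-of-fold probability and flag per index and
#'   method) and the `folds` used.
#' @export
cross_validate <- function(dataset,
                           rule = c("distributor", "promoter", "detector"),
                           methods = c("LR", "SVM", "DT", "RF", "ensemble",
                                       "cutoffA", "cutoffB"),
                           config = ensemble_config(),
                           k = 5L, fold_seed = 1L) {
  rule <- match.arg(rule)
  methods <- match.arg(methods, several.ok = TRUE)
  X <- feature_table(dataset)
  y <- rule_labels(dataset, rule)
  folds <- fold_plan(y, k, fold_seed)
  fam_of <- c(LR = "logistic-regression", SVM = "support-vector-machine",
              DT = "decision-tree", RF = "random-forest")
  ml_methods <- intersect(methods, c(names(fam_of), "ensemble"))
  cut_methods <- intersect(methods, c("cutoffA", "cutoffB"))
  scores <- score_scale(dataset$indexes[, paste0("scale_", 1:6)])
  cutoffs <- if (length(cut_methods) > 0L) find_cutoffs(scores) else NULL

  per_fold <- list()
  preds <- list()
  selected_per_fold <- vector("list", length(folds))
  for (j in seq_along(folds)) {
    test <- folds[[j]]
    train <- setdiff(seq_along(y), test)
    if (length(ml_methods) > 0L) {
      id <- fit_identifier(X[train, , drop = FALSE], y[train], config)
      Xtest <- X[test, id$selected, drop = FALSE]
      selected_per_fold[[j]] <- id$selected
    }
    for (m in methods) {
      if (m %in% names(fam_of)) {
        mod <- id$models[[fam_of[[m]]]]
        prob <- predict(mod, Xtest)
        flag <- as.integer(prob >= config$decision_threshold)
      } else if (m == "ensemble") {
        out <- ensemble_predict(id$models, config$weights, Xtest,
                                config$decision_threshold)
        prob <- out$probability
        flag <- out$label
      } else {
        which_cut <- if (m == "cutoffA") "A" else "B"
        flag <- baseline_classify(scores[test], cutoffs, which_cut)
        prob <- as.numeric(flag)
      }
      met <- classification_metrics(confusion(y[test], flag))
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(rule = rule, method = m, fold = j, t(met))
      preds[[length(preds) + 1L]] <-
        data.frame(index_id = dataset$indexes$index_id[test], rule = rule,
                   method = m, fold = j, probability = prob,
                   predicted_flag = flag, stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  avg <- do.call(rbind, lapply(split(per_fold, per_fold$method), function(d) {
    data.frame(rule = rule, method = d$method[1],
               accuracy = mean(d$accuracy), precision = mean(d$precision),
               recall = mean(d$recall), f1 = mean(d$f1))
  }))
  avg <- avg[match(methods, avg$method), ]
  rownames(avg) <- NULL
  structure(list(per_fold = per_fold, average = avg,
                 predictions = do.call(rbind, preds), folds = folds,
                 selected_per_fold = selected_per_fold,
                 rule = rule, cutoffs = cutoffs),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> rule '%s', %d folds\n", x$rule, length(x$folds)))
  print(x$average, digits = 3)
  invisible(x)
}

#' Increased percentage with the shared-total denominator
#'
#' The gain of the machine-identified set over the baseline-identified
#' set, expressed as a percentage of the *total* count (e.g. all 269
#' distributed kits), not of the machine count:
#' `100 * (n_ml - n_base) / n_total`, reported to one decimal.
#'
#' @param n_ml,n_base Counts achieved by the two strategies.
#' @param n_total Shared denominator (the total achievable count).
#' @return Percentage, rounded to one decimal.
#' @examples
#' increased_percentage(146, 97, 269)  # 18.2
#' @export
increased_percentage <- function(n_ml, n_base, n_total) {
  if (!is.numeric(n_total) || n_total <= 0) {
    stop("validation error: n_total must be a positive count", call. = FALSE)
  }
  if (n_ml > n_total || n_base > n_total) {
    stop("validation error: counts cannot exceed n_total", call. = FALSE)
  }
  round(100 * (n_ml - n_base) / n_total, 1)
}

z_crit <- function(level) qnorm(1 - (1 - level) / 2)

#' Wald confidence interval for a difference of proportions with a
#' shared denominator
#'
#' For `p1 = n_ml / n_total` and `p2 = n_base / n_total`, the interval is
#' `(p1 - p2) +/- z * sqrt(p1 (1 - p1) / n_total + p2 (1 - p2) / n_total)`,
#' reported in percent to one decimal.
#'
#' @inheritParams increased_percentage
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `estimate`, `lower`, `upper` (percent,
#'   one decimal).
#' @examples
#' wald_diff_ci(146, 97, 269)  # 18.2 (9.9, 26.5)
#' @export
wald_diff_ci <- function(n_ml, n_base, n_total, level = 0.95) {
  if (!is.numeric(n_total) || n_total <= 0) {
    stop("validation error: n_total must be a positive count", call. = FALSE)
  }
  p1 <- n_ml / n_total
  p2 <- n_base / n_total
  se <- sqrt(p1 * (1 - p1) / n_total + p2 * (1 - p2) / n_total)
  z <- z_crit(level)
  round(100 * c(estimate = p1 - p2, lower = p1 - p2 - z * se,
                upper = p1 - p2 + z * se), 1)
}

#' Confidence interval for a mean of per-fold differences
#'
#' Cross-validation fold differences are summarized as
#' `mean +/- z * sd_pop`, where `sd_pop` is the population (n-denominator)
#' standard deviation of the per-fold values — the convention that
#' reproduces the published fold-difference intervals.
#'
#' @param per_fold_diffs Numeric vector of per-fold differences
#'   (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `mean`, `lower`, `upper`, rounded to one
#'   decimal.
#' @examples
#' fold_diff_ci(c(8.1, 10.5, 13.7, 38.2, 17.7))  # 17.6 (-3.5, 38.8)
#' @export
fold_diff_ci <- function(per_fold_diffs, level = 0.95) {
  if (length(per_fold_diffs) < 2L) {
    stop("validation error: need at least 2 folds", call. = FALSE)
  }
  m <- mean(per_fold_diffs)
  sd_pop <- sqrt(mean((per_fold_diffs - m)^2))
  z <- z_crit(level)
  round(c(mean = m, lower = m - z * sd_pop, upper = m + z * sd_pop), 1)
}
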