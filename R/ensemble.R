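#' Configuration of the soft-voting ensemble identification system
#'
#' @param specs List of four [classifier_spec()] objects, one per family.
#' @param weights Four non-negative soft-voting weights (normalized to
#'   sum to 1; default equal).
#' @param decision_threshold Probability threshold for the positive
#'   class; a probability exactly at the threshold is classified
#'   positive.
#' @param top_k Ranking-prefix length for [vote_select()]; `NULL` means
#'   `ceiling(p / 3)`.
#' @param seed Seed forwarded to the stochastic base learners.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(specs = default_classifier_specs(seed),
                            weights = rep(0.25, 4),
                            decision_threshold = 0.5,
                            top_k = NULL,
                            seed = 0L) {
  if (length(specs) != 4L ||
      !all(vapply(specs, inherits, logical(1), "classifier_spec"))) {
    stop_config("specs", "must be a list of four classifier_spec objects")
  }
  if (length(weights) != length(specs)) {
    stop_config("weights", "count must equal the number of base models")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop_config("weights", "must be non-negative with a positive sum")
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop_config("decision_threshold", "must be in (0, 1)")
  }
  structure(list(specs = specs, weights = weights / sum(weights),
                 decision_threshold = decision_threshold,
                 top_k = top_k, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Soft-voting combination of class-1 probabilities
#'
#' The ensemble probability of a row is the weighted mean of the member
#' probabilities (a convex combination, so it always lies between the
#' member minimum and maximum); the predicted label is 1 when the
#' probability reaches the threshold.
#'
#' @param probs Numeric matrix, one column per member model, one row per
#'   observation.
#' @param weights Non-negative weights, one per column (normalized
#'   internally).
#' @param threshold Decision threshold in (0, 1); ties go to class 1.
#' @return List with `probability` and integer `label`.
#' @export
soft_vote <- function(probs, weights, threshold = 0.5) {
  probs <- as.matrix(probs)
  if (length(weights) != ncol(probs)) {
    stop_config("weights", "count must equal the number of probability columns")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop_config("weights", "must be non-negative with a positive sum")
  }
  w <- weights / sum(weights)
  p <- drop(probs %*% w)
  list(probability = p, label = as.integer(p >= threshold))
}

#' Combine fitted base classifiers by soft voting
#'
#' @param models List of `base_classifier` objects sharing a predictor
#'   set.
#' @param weights One non-negative weight per model.
#' @param X Feature table to predict.
#' @param threshold Decision threshold (default 0.5, ties positive).
#' @return List with `probability` and `label` per row of `X`.
#' @export
ensemble_predict <- function(models, weights, X, threshold = 0.5) {
  if (length(models) != length(weights)) {
    stop_config("weights", "count must equal the number of models")
  }
  P <- vapply(models, predict, numeric(nrow(as.data.frame(X))), newdata = X)
  soft_vote(matrix(P, ncol = length(models)), weights, threshold)
}

#' Build the predictor table of a trial dataset
#'
#' Covariates plus the six leadership-scale items, with the trial arm
#' encoded as two dummies (`arm_sdm`, `arm_sdmpr`; standard secondary
#' distribution is the reference arm). These are the inputs the
#' identification system learns from; the alter-derived outcome columns
#' are excluded.
#'
#' @param dataset A `trial_dataset` (or its `indexes` data frame).
#' @return Data frame of numeric predictors, one row per index.
#' @export
feature_table <- function(dataset) {
  idx <- if (inherits(dataset, "trial_dataset")) dataset$indexes else dataset
  drop_cols <- c("index_id", "arm", "n_alters", "n_first_time_alters",
                 "n_positive_alters", "is_key_distributor",
                 "is_key_promoter", "is_key_detector")
  X <- idx[, setdiff(names(idx), drop_cols), drop = FALSE]
  X$arm_sdm <- as.integer(idx$arm == "SD-M")
  X$arm_sdmpr <- as.integer(idx$arm == "SD-M-PR")
  check_features(X)
}

rule_labels <- function(dataset, rule = c("distributor", "promoter",
                                          "detector")) {
  rule <- match.arg(rule)
  idx <- if (inherits(dataset, "trial_dataset")) dataset$indexes else dataset
  col <- switch(rule, distributor = "is_key_distributor",
                promoter = "is_key_promoter", detector = "is_key_detector")
  if (!col %in% names(idx)) {
    stop(sprintf("validation error: dataset is not labeled (missing '%s')",
                 col), call. = FALSE)
  }
  as.integer(idx[[col]])
}

#' Fit the two-pass ensemble identification system
#'
#' Pass 1 fits all four base classifiers on the full predictor set and
#' computes each family's importance ranking; [vote_select()] intersects
#' the top-ranked prefixes to pick the predictors every model agrees
#' are important. Pass 2 refits the four classifiers on the selected
#' predictors and combines them into the soft-voting ensemble.
#'
#' @param X Feature table (e.g. from [feature_table()]).
#' @param y Binary labels for the targeted influencer rule.
#' @param config An [ensemble_config()].
#' @return An object of class `identifier`: rankings, selected
#'   predictors, refitted models and voting weights. Use [predict()] for
#'   ensemble probabilities/labels and `$models` for the individual
#'   refitted families.
#' @export
fit_identifier <- function(X, y, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  X <- check_features(X)
  pass1 <- lapply(config$specs, function(s) fit_base(s, X, y))
  rankings <- lapply(pass1, function(m) rank_predictors(m, X, y))
  selected <- vote_select(rankings, config$top_k)
  X2 <- X[, selected, drop = FALSE]
  models <- lapply(config$specs, function(s) fit_base(s, X2, y))
  structure(list(config = config, rankings = rankings,
                 selected = as.character(selected),
                 k_used = attr(selected, "k_used"), models = models),
            class = "identifier")
}

#' @export
predict.identifier <- function(object, newdata, ...) {
  X <- check_features(newdata)[, object$selected, drop = FALSE]
  ensemble_predict(object$models, object$config$weights, X,
                   object$config$decision_threshold)
}

#' @export
print.identifier <- function(x, ...) {
  cat(sprintf("<identifier> selected %d predictor(s) (k=%d): %s\n",
              length(x$selected), x$k_used,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Run the identification system on a labeled trial dataset
#'
#' Convenience wrapper: builds the feature table, fits the two-pass
#' ensemble for the requested influencer rule on the whole dataset, and
#' returns in-sample predictions for every index.
#'
#' @param dataset A labeled `trial_dataset`.
#' @param rule Influencer rule: `"distributor"`, `"promoter"` or
#'   `"detector"`.
#' @param config An [ensemble_config()].
#' @return List with the fitted `identifier` and a `predictions` data
#'   frame (`index_id`, `rule`, `probability`, `predicted_flag`).
#' @export
run_identification <- function(dataset, rule = c("distributor", "promoter",
                                                 "detector"),
                               config = ensemble_config()) {
  rule <- match.arg(rule)
  X <- feature_table(dataset)
  y <- rule_labels(dataset, rule)
  id <- fit_identifier(X, y, config)
  pred <- predict(id, X)
  list(identifier = id,
       predictions = data.frame(index_id = dataset$indexes$index_id,
                                rule = rule,
                                probability = pred$probability,
                                predicted_flag = pred$label,
                                stringsAsFactors = FALSE))
}
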