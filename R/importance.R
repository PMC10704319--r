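#' Rank predictors by a family-specific importance rule
#'
#' Each base-classifier family ranks every predictor, most important
#' first:
#' * logistic regression — absolute value of the standardized
#'   coefficient (predictors are z-scored at fit time, so coefficient
#'   magnitudes are comparable);
#' * linear SVM — recursive feature elimination (RFE): the model is
#'   refit repeatedly, each round dropping the predictor with the
#'   smallest squared weight in the primal weight vector
#'   \eqn{w = \sum_i \alpha_i y_i x_i}; the last survivor ranks first;
#' * decision tree / random forest — total Gini-impurity decrease
#'   attributable to each predictor.
#'
#' @param fitted A `base_classifier` from [fit_base()].
#' @param X,y The training feature table and binary labels (needed by
#'   the RFE loop; the other families read their fitted state).
#' @return An object of class `importance_ranking`: list with `family`,
#'   `predictors` (a permutation of the predictor set, most important
#'   first) and `scores` (non-increasing along that order).
#' @export
rank_predictors <- function(fitted, X, y) {
  stopifnot(inherits(fitted, "base_classifier"))
  X <- check_features(X)
  if (!setequal(names(X), fitted$predictors)) {
    stop("schema error: X predictors differ from the fitted model's",
         call. = FALSE)
  }
  X <- X[, fitted$predictors, drop = FALSE]
  fam <- fitted$spec$family
  rk <- switch(fam,
    "logistic-regression" = {
      cf <- coef(fitted$fit)
      cf <- abs(cf[setdiff(names(cf), "(Intercept)")])
      names(cf) <- gsub("^`|`$", "", names(cf))
      ord <- order_desc(unname(cf))
      list(predictors = names(cf)[ord], scores = unname(cf)[ord])
    },
    "support-vector-machine" = svm_rfe(fitted, X, y),
    "decision-tree" = {
      vi <- fitted$fit$variable.importance
      scores <- setNames(numeric(length(fitted$predictors)),
                         fitted$predictors)
      if (!is.null(vi)) scores[names(vi)] <- vi
      ord <- order_desc(unname(scores))
      list(predictors = names(scores)[ord], scores = unname(scores)[ord])
    },
    "random-forest" = {
      imp <- randomForest::importance(fitted$fit)[, "MeanDecreaseGini"]
      ord <- order_desc(unname(imp))
      list(predictors = names(imp)[ord], scores = unname(imp)[ord])
    }
  )
  structure(list(family = fam, predictors = rk$predictors,
                 scores = rk$scores),
            class = "importance_ranking")
}

# RFE with a linear SVM: one predictor eliminated per round; returns the
# reverse elimination order with rank-position scores (p .. 1).
svm_rfe <- function(fitted, X, y) {
  y <- coerce_binary(y)
  hp <- fitted$spec$hyperparameters
  remaining <- fitted$predictors
  eliminated <- character(0)
  pp <- make_preproc(X)
  Xs <- apply_preproc(pp, X)
  yf <- factor(y, levels = c(0, 1))
  while (length(remaining) > 1L) {
    fit <- withr::with_seed(child_seed(hp$seed, 13L, length(remaining)),
      e1071::svm(x = Xs[, remaining, drop = FALSE], y = yf,
                 kernel = "linear", cost = hp$cost, probability = FALSE,
                 scale = FALSE))
    w <- drop(crossprod(fit$coefs, fit$SV))   # primal weights
    drop_j <- which.min(w^2)
    eliminated <- c(eliminated, remaining[drop_j])
    remaining <- remaining[-drop_j]
  }
  ordered <- c(remaining, rev(eliminated))
  list(predictors = ordered, scores = as.numeric(seq(length(ordered), 1)))
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> %s: %s\n", x$family,
              paste(head(x$predictors, 6L), collapse = " > ")))
  invisible(x)
}

#' Cross-model vote on the top-ranked predictors
#'
#' The selected predictor set is the intersection of the four models'
#' top-`k` ranking prefixes — a predictor is kept only if every model
#' ranks it in its own top `k`. If the intersection is empty at the
#' requested `top_k`, `k` is incremented until it is not (at `k = p` the
#' intersection is the full set, so termination is guaranteed).
#'
#' @param rankings List of `importance_ranking` objects covering the
#'   same predictor set (normally one per family).
#' @param top_k Prefix length to intersect; default `ceiling(p / 3)`.
#' @return Character vector of selected predictors, ordered by mean rank
#'   across models, with attribute `k_used`.
#' @export
vote_select <- function(rankings, top_k = NULL) {
  stopifnot(length(rankings) >= 1L)
  sets <- lapply(rankings, `[[`, "predictors")
  p <- length(sets[[1]])
  if (!all(vapply(sets, function(s) setequal(s, sets[[1]]), logical(1)))) {
    stop("schema error: rankings cover inconsistent predictor sets",
         call. = FALSE)
  }
  if (is.null(top_k)) top_k <- ceiling(p / 3)
  if (top_k < 1L || top_k > p) {
    stop_config("top_k", sprintf("must be in 1..%d", p))
  }
  for (k in seq(top_k, p)) {
    sel <- Reduce(intersect, lapply(sets, head, k))
    if (length(sel) > 0L) {
      mean_rank <- vapply(sel, function(v) {
        mean(vapply(sets, function(s) match(v, s), numeric(1)))
      }, numeric(1))
      out <- sel[order(mean_rank, match(sel, sets[[1]]))]
      attr(out, "k_used") <- as.integer(k)
      return(out)
    }
  }
  stop("internal error: vote_select failed to terminate")  # unreachable
}
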