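#' Specify one base classifier
#'
#' The identification system uses four families: logistic regression
#' (maximum likelihood), a linear support vector machine, a CART
#' classification tree and a random forest. Hyperparameters not supplied
#' fall back to fixed defaults: SVM linear kernel with cost 1; tree with
#' minimum leaf size 5 and no complexity pruning; forest with 100 trees;
#' every family carries a `seed` (default 0) that fixes any internal
#' randomness.
#'
#' @param family One of `"logistic-regression"`,
#'   `"support-vector-machine"`, `"decision-tree"`, `"random-forest"`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param calibrate For margin-based models, fit probability calibration
#'   so the model can vote softly (default `TRUE`; the SVM uses
#'   Platt-type sigmoid calibration).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("logistic-regression",
                                       "support-vector-machine",
                                       "decision-tree", "random-forest"),
                            hyperparameters = list(),
                            calibrate = TRUE) {
  family <- match.arg(family)
  defaults <- switch(family,
    "logistic-regression" = list(maxit = 100, seed = 0L),
    "support-vector-machine" = list(cost = 1, seed = 0L),
    "decision-tree" = list(minbucket = 5, minsplit = 10, cp = 0,
                           maxdepth = 30, seed = 0L),
    "random-forest" = list(ntree = 100, seed = 0L)
  )
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown) > 0L) {
    stop_config("hyperparameters",
                sprintf("has entries unknown to family '%s': %s", family,
                        paste(unknown, collapse = ", ")))
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 calibrate = isTRUE(calibrate)),
            class = "classifier_spec")
}

#' Default specifications of the four base classifiers
#' @param seed Seed shared by the stochastic families.
#' @return List of four [classifier_spec()] objects named by family.
#' @export
default_classifier_specs <- function(seed = 0L) {
  fams <- c("logistic-regression", "support-vector-machine",
            "decision-tree", "random-forest")
  setNames(lapply(fams, function(f) {
    classifier_spec(f, hyperparameters = list(seed = as.integer(seed)))
  }), fams)
}

check_features <- function(X) {
  X <- as.data.frame(X)
  if (anyNA(X)) {
    stop("validation error: feature table contains missing values; impute before fitting",
         call. = FALSE)
  }
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("validation error: all predictors must be numeric (encode factors as dummies)",
         call. = FALSE)
  }
  X
}

# standardize continuous columns on the training split; 0/1 columns pass
# through untouched (needed both for standardized LR coefficients and
# for the SVM margin geometry)
make_preproc <- function(X) {
  binary <- vapply(X, is_binary_col, logical(1))
  center <- vapply(X, mean, numeric(1))
  scl <- vapply(X, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  center[binary] <- 0
  scl[binary] <- 1
  list(center = center, scale = scl)
}

apply_preproc <- function(pp, X) {
  X <- as.data.frame(X)
  for (j in names(pp$center)) {
    X[[j]] <- (X[[j]] - pp$center[[j]]) / pp$scale[[j]]
  }
  as.matrix(X[, names(pp$center), drop = FALSE])
}

#' Fit one base classifier
#'
#' Continuous predictors are z-scored on the training data (binary
#' left as 0/1); the fitted transform travels with the model and is
#' re-applied at prediction time.
#'
#' @param spec A [classifier_spec()].
#' @param X Feature table (data frame of numeric predictors, no missing
#'   values).
#' @param y Binary labels (0/1, logical, or 2-level factor); the positive
#'   class is the key influencer.
#' @return An object of class `base_classifier` that [predict()] maps to
#'   class-1 probabilities.
#' @export
fit_base <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- check_features(X)
  y <- coerce_binary(y)
  if (length(y) != nrow(X)) {
    stop("validation error: X and y lengths differ", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("degenerate-label error: y contains a single class", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("validation error: need at least 2 rows per class", call. = FALSE)
  }
  pp <- make_preproc(X)
  Xs <- apply_preproc(pp, X)
  hp <- spec$hyperparameters
  fit <- withr::with_seed(child_seed(hp$seed, 11L), switch(spec$family,
    "logistic-regression" = {
      df <- data.frame(Xs, check.names = FALSE)
      df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           control = list(maxit = hp$maxit)))
    },
    "support-vector-machine" = e1071::svm(
      x = Xs, y = factor(y, levels = c(0, 1)), kernel = "linear",
      cost = hp$cost, probability = spec$calibrate, scale = FALSE
    ),
    "decision-tree" = {
      df <- data.frame(Xs, check.names = FALSE)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minbucket = hp$minbucket, minsplit = hp$minsplit,
                     cp = hp$cp, maxdepth = hp$maxdepth, xval = 0))
    },
    "random-forest" = randomForest::randomForest(
      x = Xs, y = factor(y, levels = c(0, 1)), ntree = hp$ntree
    )
  ))
  structure(list(spec = spec, fit = fit, preproc = pp,
                 predictors = colnames(Xs)),
            class = "base_classifier")
}

#' Predict class-1 probabilities from a fitted base classifier
#'
#' @param object A `base_classifier` from [fit_base()].
#' @param newdata Feature table with the same predictors used in
#'   training.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities in \[0, 1\].
#' @export
predict.base_classifier <- function(object, newdata, ...) {
  newdata <- check_features(newdata)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing) > 0L) {
    stop(sprintf("schema error: newdata lacks predictor(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  Xs <- apply_preproc(object$preproc, newdata)
  switch(object$spec$family,
    "logistic-regression" = {
      unname(predict(object$fit, newdata = data.frame(Xs, check.names = FALSE),
                     type = "response"))
    },
    "support-vector-machine" = {
      if (object$spec$calibrate) {
        pr <- predict(object$fit, Xs, probability = TRUE)
        unname(attr(pr, "probabilities")[, "1"])
      } else {
        # uncalibrated fallback: squash the decision value
        dvm <- attr(predict(object$fit, Xs, decision.values = TRUE),
                    "decision.values")
        sgn <- if (identical(colnames(dvm), "0/1")) -1 else 1
        unname(plogis(sgn * dvm[, 1]))
      }
    },
    "decision-tree" = {
      unname(predict(object$fit, newdata = data.frame(Xs, check.names = FALSE),
                     type = "prob")[, "1"])
    },
    "random-forest" = {
      unname(predict(object$fit, newdata = Xs, type = "prob")[, "1"])
    }
  )
}

#' @export
print.base_classifier <- function(x, ...) {
  cat(sprintf("<base_classifier> %s on %d predictors\n", x$spec$family,
              length(x$predictors)))
  invisible(x)
}
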