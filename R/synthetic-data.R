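#' Default covariate schema for the synthetic generator
#'
#' The predictor set of the motivating trial is not public, so the
#' generator ships a plausible schema for an MSM HIVST secondary
#' distribution survey: demographics, testing history, sexual network
#' size, app use and disclosure status. Every entry is a list with a
#' `name`, a `kind` (`"binary"`, `"ordinal"` or `"continuous"`) and the
#' distribution parameters for that kind (`prob`; `values` + `probs`;
#' `mean` + `sd` or `meanlog` + `sdlog` with `dist = "lognormal"`).
#'
#' @return A list of covariate specification entries.
#' @export
default_covariates <- function() {
  list(
    list(name = "age", kind = "continuous", mean = 30, sd = 8),
    list(name = "education", kind = "ordinal", values = 1:4,
         probs = c(0.15, 0.35, 0.35, 0.15)),
    list(name = "income", kind = "ordinal", values = 1:5,
         probs = c(0.2, 0.25, 0.25, 0.2, 0.1)),
    list(name = "ever_tested", kind = "binary", prob = 0.7),
    list(name = "months_since_last_test", kind = "continuous",
         dist = "lognormal", meanlog = 1.8, sdlog = 0.8),
    list(name = "n_partners", kind = "ordinal", values = 0:5,
         probs = c(0.25, 0.3, 0.2, 0.12, 0.08, 0.05)),
    list(name = "app_use_freq", kind = "ordinal", values = 0:4,
         probs = c(0.15, 0.2, 0.25, 0.25, 0.15)),
    list(name = "disclosed", kind = "binary", prob = 0.5)
  )
}

#' Default propensity model for the synthetic generator
#'
#' Linear weights, on z-scored covariates, of the latent distribution
#' propensity \eqn{\theta_i = \mathrm{logit}^{-1}(b_0 + \sum_j \beta_j
#' z_{ij})}. Nonzero weights plant signal in app use frequency, partner
#' number, testing history and education; the remaining covariates are
#' noise predictors. The intercept, together with the zero-inflated
#' Poisson parameters in [generator_config()], was calibrated numerically
#' so that the expected marginals match the trial's published counts.
#'
#' @return A list with elements `intercept` and `coefficients` (named
#'   numeric vector over covariate names).
#' @export
default_propensity <- function() {
  list(
    intercept = -4.0325,
    coefficients = c(
      age = 0, education = 0.3, income = 0, ever_tested = 0.5,
      months_since_last_test = -0.2, n_partners = 0.7,
      app_use_freq = 0.9, disclosed = 0
    )
  )
}

#' Configuration of the synthetic trial-data generator
#'
#' Defaults are calibrated so that, in expectation over seeds, a
#' generated dataset reproduces the motivating trial's published
#' marginals: 309 indexes distributing to about 269 alters, about 60 key
#' distributors (>= 2 alters), 73 key promoters, 23 key detectors, 103
#' first-time-tester alters and 25 HIV-positive alters.
#'
#' @param n_indexes Number of index participants (default 309).
#' @param covariates Covariate schema, see [default_covariates()].
#' @param propensity Propensity model, see [default_propensity()].
#' @param scale_signal Correlation strength in \[0, 1\] between the latent
#'   distribution propensity and the 6 leadership-scale items. At 0 the
#'   scale is pure noise; at 1 the item-generating trait is the
#'   standardized propensity itself.
#' @param alter_zero_inflation Zero-inflation probability \eqn{\pi_0} of
#'   the alter-count model.
#' @param alter_mu Poisson rate scale \eqn{\mu}; index \eqn{i} draws its
#'   alter count from a zero-inflated Poisson with rate
#'   \eqn{2\mu\theta_i}.
#' @param p_first_time Probability an alter is a first-time tester
#'   (default 103/269, the trial's alter-level rate).
#' @param p_positive Probability an alter tests HIV-positive
#'   (default 25/269).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_indexes = 309,
                             covariates = default_covariates(),
                             propensity = default_propensity(),
                             scale_signal = 0.5,
                             alter_zero_inflation = 0.0532,
                             alter_mu = 13.007,
                             p_first_time = 103 / 269,
                             p_positive = 25 / 269,
                             seed = 1L) {
  if (!is.numeric(n_indexes) || length(n_indexes) != 1L || n_indexes < 10) {
    stop_config("n_indexes", "must be a single count >= 10")
  }
  if (!is.list(covariates) || length(covariates) == 0L) {
    stop_config("covariates", "must be a non-empty list of covariate specs")
  }
  cov_names <- vapply(covariates, function(cv) cv$name, character(1))
  if (anyDuplicated(cov_names)) {
    stop_config("covariates", "has duplicated covariate names")
  }
  for (cv in covariates) {
    if (!cv$kind %in% c("binary", "ordinal", "continuous")) {
      stop_config("covariates", sprintf("entry '%s' has unknown kind '%s'",
                                        cv$name, cv$kind))
    }
    if (cv$kind == "binary") check_prob(cv$prob, paste0(cv$name, "$prob"))
    if (cv$kind == "ordinal" && length(cv$values) != length(cv$probs)) {
      stop_config("covariates",
                  sprintf("entry '%s' values/probs length mismatch", cv$name))
    }
  }
  coefs <- propensity$coefficients
  if (is.null(names(coefs)) || !all(names(coefs) %in% cov_names)) {
    stop_config("propensity",
                "coefficients must be named after covariates in the schema")
  }
  if (!is.numeric(scale_signal) || scale_signal < 0 || scale_signal > 1) {
    stop_config("scale_signal", "must be in [0, 1]")
  }
  check_prob(alter_zero_inflation, "alter_zero_inflation")
  check_prob(p_first_time, "p_first_time")
  check_prob(p_positive, "p_positive")
  if (!is.numeric(alter_mu) || alter_mu < 0) {
    stop_config("alter_mu", "must be >= 0")
  }
  structure(
    list(n_indexes = as.integer(n_indexes), covariates = covariates,
         propensity = propensity, scale_signal = scale_signal,
         alter_zero_inflation = alter_zero_inflation, alter_mu = alter_mu,
         p_first_time = p_first_time, p_positive = p_positive,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

draw_covariate <- function(cv, n) {
  switch(cv$kind,
    binary = rbinom(n, 1L, cv$prob),
    ordinal = sample(cv$values, n, replace = TRUE, prob = cv$probs),
    continuous = if (identical(cv$dist, "lognormal")) {
      rlnorm(n, cv$meanlog, cv$sdlog)
    } else {
      rnorm(n, cv$mean, cv$sd)
    }
  )
}

# z-score with a zero-variance guard
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Leadership-scale item marginal: probabilities of responses 0..4,
# chosen so scale totals clump just above the 80th percentile (trial-like
# tie structure around the top-20% cutoff).
scale_item_probs <- c(0.40, 0.27, 0.18, 0.10, 0.05)
scale_item_loading <- 0.45

#' Generate a synthetic secondary-distribution trial dataset
#'
#' Draws covariates for `n_indexes` index participants, forms a latent
#' distribution propensity \eqn{\theta_i} from the propensity model,
#' draws each index's alter count from a zero-inflated Poisson with rate
#' \eqn{2\mu\theta_i}, flags each alter independently as a first-time
#' tester and/or HIV-positive, draws the six 0-4 leadership-scale items
#' from a discretized latent-Gaussian trait correlated with the
#' propensity at strength `scale_signal`, and derives the three
#' key-influencer labels from the alter counts.
#'
#' @param config A [generator_config()].
#' @return An object of class `trial_dataset`: a list with data frames
#'   `indexes` (one row per index) and `alters` (one row per kit
#'   recipient), the `config`, and the `seed` used.
#' @examples
#' ds <- generate_trial(generator_config(n_indexes = 50, seed = 7))
#' table(ds$indexes$is_key_distributor)
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  n <- config$n_indexes
  withr::with_seed(child_seed(config$seed, 1L), {
    covs <- lapply(config$covariates, draw_covariate, n = n)
    names(covs) <- vapply(config$covariates, `[[`, character(1), "name")
    arm <- sample(c("SD", "SD-M", "SD-M-PR"), n, replace = TRUE)
  })

  Z <- vapply(covs, zscore, numeric(n))
  coefs <- config$propensity$coefficients
  eta <- drop(Z[, names(coefs), drop = FALSE] %*% coefs)
  theta <- plogis(config$propensity$intercept + eta)

  withr::with_seed(child_seed(config$seed, 2L), {
    lambda <- 2 * config$alter_mu * theta
    n_alters <- ifelse(runif(n) < config$alter_zero_inflation, 0L,
                       rpois(n, lambda))
  })

  index_id <- sprintf("I%04d", seq_len(n))
  total_alters <- sum(n_alters)
  withr::with_seed(child_seed(config$seed, 3L), {
    alters <- data.frame(
      alter_id = sprintf("A%04d", seq_len(total_alters)),
      index_id = rep(index_id, n_alters),
      is_first_time = rbinom(total_alters, 1L, config$p_first_time),
      is_positive = rbinom(total_alters, 1L, config$p_positive),
      stringsAsFactors = FALSE
    )
  })

  ss <- config$scale_signal
  withr::with_seed(child_seed(config$seed, 4L), {
    trait <- ss * zscore(eta) + sqrt(1 - ss^2) * rnorm(n)
    cuts <- qnorm(cumsum(scale_item_probs))[1:4]
    items <- vapply(1:6, function(j) {
      z <- scale_item_loading * trait +
        sqrt(1 - scale_item_loading^2) * rnorm(n)
      findInterval(z, cuts)
    }, numeric(n))
  })
  colnames(items) <- paste0("scale_", 1:6)

  indexes <- data.frame(index_id = index_id, arm = arm,
                        as.data.frame(covs), items,
                        stringsAsFactors = FALSE)
  indexes <- derive_labels(indexes, alters)
  structure(list(indexes = indexes, alters = alters, config = config,
                 seed = config$seed),
            class = "trial_dataset")
}

#' Recompute alter counts and key-influencer labels
#'
#' Tallies each index's alters from the alter table and sets the three
#' label flags by definition: key distributor iff >= 2 alters, key
#' promoter iff >= 1 first-time-tester alter, key detector iff >= 1
#' HIV-positive alter. Idempotent; any existing count/label columns are
#' overwritten.
#'
#' @param indexes Index data frame with an `index_id` column.
#' @param alters Alter data frame with `alter_id`, `index_id`,
#'   `is_first_time`, `is_positive`.
#' @return `indexes` with columns `n_alters`, `n_first_time_alters`,
#'   `n_positive_alters`, `is_key_distributor`, `is_key_promoter`,
#'   `is_key_detector` recomputed.
#' @export
derive_labels <- function(indexes, alters) {
  bad <- setdiff(alters$index_id, indexes$index_id)
  if (length(bad) > 0L) {
    stop(sprintf("integrity error: alter table references unknown index id(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  tally <- function(w) {
    t <- tapply(w, alters$index_id, sum)
    out <- setNames(integer(nrow(indexes)), indexes$index_id)
    out[names(t)] <- as.integer(t)
    unname(out)
  }
  indexes$n_alters <- tally(rep(1L, nrow(alters)))
  indexes$n_first_time_alters <- tally(alters$is_first_time)
  indexes$n_positive_alters <- tally(alters$is_positive)
  indexes$is_key_distributor <- as.integer(indexes$n_alters >= 2L)
  indexes$is_key_promoter <- as.integer(indexes$n_first_time_alters >= 1L)
  indexes$is_key_detector <- as.integer(indexes$n_positive_alters >= 1L)
  indexes
}

#' Write / read a trial dataset as delimited text
#'
#' `write_dataset()` writes `indexes.csv`, `alters.csv` and `config.json`
#' into `path`; doubles are written with full precision so the round trip
#' is exact. `read_dataset()` reads them back, re-validates alter
#' references and recomputes labels.
#'
#' @param dataset A `trial_dataset`.
#' @param path Directory to write to / read from (created if absent).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `trial_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- format_double(df[[j]])
    }
    df
  }
  write.csv(fmt(dataset$indexes), file.path(path, "indexes.csv"),
            row.names = FALSE, quote = TRUE)
  write.csv(fmt(dataset$alters), file.path(path, "alters.csv"),
            row.names = FALSE, quote = TRUE)
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  fidx <- file.path(path, "indexes.csv")
  falt <- file.path(path, "alters.csv")
  for (f in c(fidx, falt)) {
    if (!file.exists(f)) stop(sprintf("parse error: missing file '%s'", f),
                              call. = FALSE)
  }
  indexes <- read.csv(fidx, stringsAsFactors = FALSE)
  alters <- read.csv(falt, stringsAsFactors = FALSE)
  need_i <- c("index_id", "arm")
  if (!all(need_i %in% names(indexes))) {
    stop(sprintf("parse error in '%s' line 1: missing column(s) %s", fidx,
                 paste(setdiff(need_i, names(indexes)), collapse = ", ")),
         call. = FALSE)
  }
  need_a <- c("alter_id", "index_id", "is_first_time", "is_positive")
  if (nrow(alters) > 0L && !all(need_a %in% names(alters))) {
    stop(sprintf("parse error in '%s' line 1: missing column(s) %s", falt,
                 paste(setdiff(need_a, names(alters)), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(alters) == 0L) {
    alters <- data.frame(alter_id = character(), index_id = character(),
                         is_first_time = integer(), is_positive = integer(),
                         stringsAsFactors = FALSE)
  }
  bad <- which(!alters$index_id %in% indexes$index_id)
  if (length(bad) > 0L) {
    stop(sprintf("integrity error in '%s' line %d: alter '%s' references unknown index '%s'",
                 falt, bad[1] + 1L, alters$alter_id[bad[1]],
                 alters$index_id[bad[1]]), call. = FALSE)
  }
  # config round-trip is best-effort; the dataset itself is authoritative
  fcfg <- file.path(path, "config.json")
  cfg <- if (file.exists(fcfg)) {
    tryCatch({
      raw <- jsonlite::fromJSON(fcfg, simplifyDataFrame = FALSE)
      raw$propensity$coefficients <- unlist(raw$propensity$coefficients)
      do.call(generator_config, raw)
    }, error = function(e) NULL)
  }
  indexes <- derive_labels(indexes, alters)
  structure(list(indexes = indexes, alters = alters, config = cfg,
                 seed = if (!is.null(cfg)) cfg$seed else NA_integer_),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> %d indexes, %d alters | distributors %d, promoters %d, detectors %d\n",
    nrow(x$indexes), nrow(x$alters), sum(x$indexes$is_key_distributor),
    sum(x$indexes$is_key_promoter), sum(x$indexes$is_key_detector)))
  invisible(x)
}
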