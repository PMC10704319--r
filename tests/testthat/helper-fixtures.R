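# Shared fixtures, all generated in code.

# a fast, small trial dataset for structural tests
quick_dataset <- function(seed = 1L, n = 80L, ...) {
  generate_trial(generator_config(n_indexes = n, seed = seed, ...))
}

# features with planted signal in p1, p2 and pure-noise columns
planted_features <- function(n, seed = 1L, beta = c(1.2, -1.0),
                             n_noise = 3L) {
  withr::with_seed(seed, {
    X <- data.frame(p1 = rnorm(n), p2 = rnorm(n))
    for (j in seq_len(n_noise)) X[[paste0("noise", j)]] <- rnorm(n)
    y <- rbinom(n, 1, plogis(beta[1] * X$p1 + beta[2] * X$p2))
    list(X = X, y = y)
  })
}

# a hand-made importance ranking
fake_ranking <- function(predictors, family = "decision-tree") {
  structure(list(family = family, predictors = predictors,
                 scores = as.numeric(rev(seq_along(predictors)))),
            class = "importance_ranking")
}

# index/alter tables engineered to the published label totals:
# 309 indexes, 269 alters, 60 distributors, 73 promoters (103 first-time
# alters), 23 detectors (25 positive alters)
trial_shaped_tables <- function() {
  indexes <- data.frame(index_id = sprintf("I%03d", 1:309),
                        stringsAsFactors = FALSE)
  owner <- c(rep(1:60, each = 2), 61:209)           # 60x2 + 149x1 = 269
  alters <- data.frame(
    alter_id = sprintf("A%03d", seq_along(owner)),
    index_id = indexes$index_id[owner],
    is_first_time = 0L, is_positive = 0L,
    stringsAsFactors = FALSE
  )
  # promoters: indexes 1..30 (both alters first-time) + 61..103 -> 73
  alters$is_first_time[owner %in% 1:30] <- 1L            # 60 alters
  alters$is_first_time[match(61:103, owner)] <- 1L       # 43 alters
  # detectors: indexes 1..2 (both alters positive) + 61..81 -> 23
  alters$is_positive[owner %in% 1:2] <- 1L               # 4 alters
  alters$is_positive[match(61:81, owner)] <- 1L          # 21 alters
  list(indexes = indexes, alters = alters)
}
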