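test_that("degenerate alter-count models yield no influencers", {
  ds0 <- generate_trial(generator_config(n_indexes = 40, alter_mu = 0,
                                         seed = 3))
  expect_true(all(ds0$indexes$n_alters == 0))
  ds1 <- generate_trial(generator_config(n_indexes = 40,
                                         alter_zero_inflation = 1, seed = 3))
  expect_true(all(ds1$indexes$n_alters == 0))
  for (ds in list(ds0, ds1)) {
    expect_equal(sum(ds$indexes$is_key_distributor), 0)
    expect_equal(sum(ds$indexes$is_key_promoter), 0)
    expect_equal(sum(ds$indexes$is_key_detector), 0)
    expect_equal(nrow(ds$alters), 0)
  }
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(n_indexes = 5), "n_indexes")
  expect_error(generator_config(alter_mu = -1), "alter_mu")
  expect_error(generator_config(p_first_time = 1.2), "p_first_time")
  expect_error(generator_config(scale_signal = 2), "scale_signal")
  expect_error(
    generator_config(propensity = list(intercept = 0,
                                       coefficients = c(bogus = 1))),
    "propensity")
})

test_that("default config gives a trial-like key-distributor fraction", {
  for (seed in c(1, 7, 19)) {
    ds <- generate_trial(generator_config(seed = seed))
    frac <- mean(ds$indexes$is_key_distributor)
    expect_gte(frac, 0.10)
    expect_lte(frac, 0.30)
  }
})

test_that("dataset internal consistency: counts agree with the alter table", {
  ds <- quick_dataset(seed = 11, n = 120)
  expect_equal(sum(ds$indexes$n_alters), nrow(ds$alters))
  tab <- table(factor(ds$alters$index_id, levels = ds$indexes$index_id))
  expect_equal(ds$indexes$n_alters, as.integer(tab))
  expect_true(all(ds$indexes$n_first_time_alters <= ds$indexes$n_alters))
  expect_true(all(ds$indexes$n_positive_alters <= ds$indexes$n_alters))
  expect_true(all(vapply(ds$indexes[, paste0("scale_", 1:6)],
                         function(x) all(x %in% 0:4), logical(1))))
})

test_that("derive_labels implements the biconditional definitions and is idempotent", {
  idx <- data.frame(index_id = c("I1", "I2", "I3"), stringsAsFactors = FALSE)
  alt <- data.frame(alter_id = c("A1", "A2", "A3"),
                    index_id = c("I1", "I1", "I2"),
                    is_first_time = c(0L, 0L, 1L),
                    is_positive = c(0L, 0L, 1L), stringsAsFactors = FALSE)
  out <- derive_labels(idx, alt)
  # I1: two ordinary alters -> distributor only
  expect_equal(unlist(out[1, c("is_key_distributor", "is_key_promoter",
                               "is_key_detector")], use.names = FALSE),
               c(1L, 0L, 0L))
  # I2: one positive first-time alter -> promoter and detector
  expect_equal(unlist(out[2, c("is_key_distributor", "is_key_promoter",
                               "is_key_detector")], use.names = FALSE),
               c(0L, 1L, 1L))
  # I3: no alters
  expect_equal(out$n_alters[3], 0L)
  expect_identical(derive_labels(out, alt), out)

  ds <- quick_dataset(seed = 5)
  expect_identical(derive_labels(ds$indexes, ds$alters), ds$indexes)

  bad <- alt; bad$index_id[2] <- "I99"
  expect_error(derive_labels(idx, bad), "integrity error")
})

test_that("a trial-shaped alter table reproduces the published label totals", {
  tabs <- trial_shaped_tables()
  out <- derive_labels(tabs$indexes, tabs$alters)
  expect_equal(nrow(tabs$alters), 269)
  expect_equal(sum(out$is_key_distributor), 60)
  expect_equal(sum(out$is_key_promoter), 73)
  expect_equal(sum(out$is_key_detector), 23)
  expect_equal(sum(out$n_first_time_alters), 103)
  expect_equal(sum(out$n_positive_alters), 25)
})

test_that("datasets round-trip through disk exactly and deterministically", {
  ds <- quick_dataset(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  back <- read_dataset(d1)
  expect_equal(back$indexes, ds$indexes)
  expect_equal(back$alters, ds$alters)

  # identical config + seed => byte-identical files
  write_dataset(generate_trial(ds$config), d2)
  for (f in c("indexes.csv", "alters.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("reading a dataset with dangling alter references fails with a line number", {
  ds <- quick_dataset(seed = 8)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  alt <- read.csv(file.path(d, "alters.csv"), stringsAsFactors = FALSE)
  alt$index_id[3] <- "I9999"
  write.csv(alt, file.path(d, "alters.csv"), row.names = FALSE)
  expect_error(read_dataset(d), "integrity error.*line 4")
  expect_error(read_dataset(file.path(d, "nope")), "parse error")
})

test_that("an empty alter table reads back as a dataset with no alters", {
  ds <- quick_dataset(seed = 4, alter_mu = 0)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_dataset(d)
  expect_equal(nrow(back$alters), 0)
  expect_true(all(back$indexes$n_alters == 0))
})

test_that("scale informativeness tracks scale_signal", {
  cors <- vapply(1:20, function(s) {
    ds <- generate_trial(generator_config(n_indexes = 150, seed = s,
                                          scale_signal = 0.5))
    tot <- score_scale(ds$indexes[, paste0("scale_", 1:6)])
    suppressWarnings(cor(tot, ds$indexes$n_alters, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(cors), 0.1)
  expect_true(all(cors > 0))

  cors0 <- vapply(1:20, function(s) {
    ds <- generate_trial(generator_config(n_indexes = 150, seed = s,
                                          scale_signal = 0))
    tot <- score_scale(ds$indexes[, paste0("scale_", 1:6)])
    suppressWarnings(cor(tot, ds$indexes$n_alters, method = "spearman"))
  }, numeric(1))
  # zero signal: mean rank correlation within Monte-Carlo noise of zero
  expect_lt(abs(mean(cors0)), 3 / sqrt(20 * 150))
})
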