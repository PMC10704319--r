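test_that("confusion counts match a per-element tally oracle", {
  for (s in 1:10) {
    pair <- withr::with_seed(s, list(t = rbinom(20, 1, 0.4),
                                     p = rbinom(20, 1, 0.5)))
    cc <- confusion(pair$t, pair$p)
    tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (i in 1:20) {
      k <- if (pair$t[i] == 1 && pair$p[i] == 1) "tp"
           else if (pair$t[i] == 0 && pair$p[i] == 1) "fp"
           else if (pair$t[i] == 0 && pair$p[i] == 0) "tn"
           else "fn"
      tally[k] <- tally[k] + 1
    }
    expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
                 tally[c("tp", "fp", "tn", "fn")],
                 ignore_attr = TRUE)
  }
  expect_error(confusion(c(0, 1), c(1)), "lengths differ")
  cc <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(cc$fp + cc$fn, 0)
  cc <- confusion(c(1, 0), c(0, 1))
  expect_equal(cc$tp + cc$tn, 0)
})

test_that("metrics follow the standard formulas and zero conventions", {
  m <- classification_metrics(list(tp = 8, fp = 2, fn = 4, tn = 6))
  expect_equal(m[["precision"]], 0.8)
  expect_equal(m[["recall"]], 2 / 3)
  expect_equal(m[["f1"]], 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  expect_equal(m[["accuracy"]], 0.7)

  perfect <- classification_metrics(list(tp = 5, fp = 0, fn = 0, tn = 15))
  expect_equal(unname(perfect), rep(1, 4))

  degen <- classification_metrics(list(tp = 0, fp = 0, fn = 3, tn = 17))
  expect_equal(degen[["precision"]], 0)
  expect_equal(degen[["f1"]], 0)
})

test_that("f1 <= geometric <= arithmetic mean of precision and recall", {
  for (s in 1:50) {
    cnt <- withr::with_seed(s, as.list(setNames(rpois(4, 8) + 1,
                                                c("tp", "fp", "tn", "fn"))))
    m <- classification_metrics(cnt)
    p <- m[["precision"]]; r <- m[["recall"]]
    expect_lte(m[["f1"]], sqrt(p * r) + 1e-12)
    expect_lte(sqrt(p * r), (p + r) / 2 + 1e-12)
    n <- Reduce(`+`, cnt)
    expect_equal(m[["accuracy"]], 1 - (cnt$fp + cnt$fn) / n)
  }
})

test_that("fold plans partition the data with stratification", {
  for (s in 1:10) {
    y <- withr::with_seed(s, rbinom(83, 1, 0.15))
    folds <- fold_plan(y, k = 5, seed = s)
    expect_setequal(unlist(folds), seq_along(y))
    expect_equal(sum(lengths(folds)), length(y))
    sizes <- lengths(folds)
    expect_lte(max(sizes) - min(sizes), 1)
    pos_per_fold <- vapply(folds, function(f) sum(y[f]), numeric(1))
    expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  }
})

test_that("cross-validation output is structurally complete and deterministic", {
  ds <- quick_dataset(seed = 9, n = 100)
  cv1 <- cross_validate(ds, "distributor",
                        methods = c("DT", "ensemble", "cutoffA", "cutoffB"),
                        config = ensemble_config(seed = 1), fold_seed = 2)
  expect_equal(nrow(cv1$per_fold), 4 * 5)
  expect_equal(nrow(cv1$average), 4)
  # averages are unweighted fold means
  for (m in cv1$average$method) {
    expect_equal(cv1$average$accuracy[cv1$average$method == m],
                 mean(cv1$per_fold$accuracy[cv1$per_fold$method == m]))
  }
  # every index predicted exactly once per method (out of fold)
  tab <- table(cv1$predictions$method, cv1$predictions$index_id)
  expect_true(all(tab == 1))
  cv2 <- cross_validate(ds, "distributor",
                        methods = c("DT", "ensemble", "cutoffA", "cutoffB"),
                        config = ensemble_config(seed = 1), fold_seed = 2)
  expect_equal(cv1$per_fold, cv2$per_fold)
})

test_that("increased percentage uses the shared-total denominator", {
  expect_equal(increased_percentage(146, 97, 269), 18.2)
  expect_equal(increased_percentage(33, 19, 103), 13.6)
  expect_equal(increased_percentage(11, 8, 25), 12.0)
  # antisymmetry
  for (s in 1:20) {
    v <- withr::with_seed(s, sample(0:50, 2))
    expect_equal(increased_percentage(v[1], v[2], 60),
                 -increased_percentage(v[2], v[1], 60))
  }
  expect_error(increased_percentage(1, 1, 0), "n_total")
  expect_error(increased_percentage(10, 1, 5), "exceed")
})

test_that("Wald difference CI matches the published intervals and scaling law", {
  expect_equal(unname(wald_diff_ci(146, 97, 269)), c(18.2, 9.9, 26.5))
  expect_equal(unname(wald_diff_ci(11, 8, 25)), c(12.0, -14.7, 38.7))
  expect_equal(unname(wald_diff_ci(33, 19, 103)), c(13.6, 1.9, 25.3))
  # equal counts: symmetric about zero
  ci <- wald_diff_ci(20, 20, 80)
  expect_equal(ci[["estimate"]], 0)
  expect_equal(ci[["lower"]], -ci[["upper"]])
  # width shrinks as 1/sqrt(n_total) at fixed proportions
  w1 <- diff(wald_diff_ci(60, 40, 100)[c("lower", "upper")])
  w4 <- diff(wald_diff_ci(240, 160, 400)[c("lower", "upper")])
  expect_equal(unname(w1 / w4), 2, tolerance = 0.02)
})

test_that("fold-difference CI uses the population-SD convention", {
  ci <- fold_diff_ci(c(8.1, 10.5, 13.7, 38.2, 17.7))
  expect_equal(unname(ci), c(17.6, -3.5, 38.8))
  expect_equal(unname(fold_diff_ci(rep(4.2, 5))), c(4.2, 4.2, 4.2))
  pos <- fold_diff_ci(c(1, 5, 9, 2, 3))
  neg <- fold_diff_ci(-c(1, 5, 9, 2, 3))
  expect_equal(unname(pos), (-unname(neg))[c(1, 3, 2)])
  expect_error(fold_diff_ci(3), "at least 2")
})
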