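star_network <- function(n_alters = 4) {
  idx <- data.frame(index_id = "I1", stringsAsFactors = FALSE)
  alt <- data.frame(alter_id = paste0("A", seq_len(n_alters)),
                    index_id = "I1", is_first_time = 0L, is_positive = 0L,
                    stringsAsFactors = FALSE)
  build_network(idx, alt)
}

test_that("network construction counts nodes and edges correctly", {
  idx <- data.frame(index_id = c("I1", "I2", "I3"), stringsAsFactors = FALSE)
  alt <- data.frame(alter_id = c("A1", "A2", "A3"),
                    index_id = c("I1", "I1", "I2"),
                    stringsAsFactors = FALSE)
  net <- build_network(idx, alt)
  expect_equal(igraph::vcount(net), 6)
  expect_equal(igraph::ecount(net), 3)
  expect_true(igraph::is_bipartite(net))

  empty <- build_network(idx[0, , drop = FALSE], alt[0, , drop = FALSE])
  expect_equal(igraph::vcount(empty), 0)

  expect_error(build_network(idx, data.frame(alter_id = "A9",
                                             index_id = "I9")),
               "integrity error")
})

test_that("the trial-shaped dataset yields a 309+269 node network", {
  tabs <- trial_shaped_tables()
  net <- build_network(tabs$indexes, tabs$alters)
  expect_equal(igraph::vcount(net), 309 + 269)
  expect_equal(igraph::ecount(net), 269)
})

test_that("no seeds means no testing and zero efficiency", {
  net <- star_network()
  res <- simulate_distribution(net, character(0), simulation_config(seed = 1))
  expect_equal(res$efficiency, 0)
  expect_equal(nrow(res$transfers), 0)
  expect_error(simulate_distribution(net, "I99", simulation_config()),
               "unknown seed")
})

test_that("a seeded star saturates with high probability", {
  net <- star_network(4)
  eff <- vapply(1:200, function(s) {
    simulate_distribution(net, "I1",
                          simulation_config(seed = s))$efficiency
  }, numeric(1))
  expect_gte(mean(eff == 100), 0.9)
})

test_that("first-step transfers match the capped-Poisson enumeration oracle", {
  # one index, one alter, 4 kits: transfers = min(Poisson(4), 4, 1)
  net <- star_network(1)
  cfg <- function(s) simulation_config(max_steps = 1, seed = s)
  sim_mean <- mean(vapply(1:2000, function(s) {
    nrow(simulate_distribution(net, "I1", cfg(s))$transfers)
  }, numeric(1)))
  dmax <- 50
  oracle <- sum(dpois(0:dmax, 4) * pmin(0:dmax, 4, 1))
  se <- sqrt(oracle * (1 - oracle) / 2000)   # Bernoulli outcome here
  expect_lt(abs(sim_mean - oracle), 4 * se)
})

test_that("kits are conserved and transfers respect bipartite edges", {
  for (s in 1:10) {
    ds <- quick_dataset(seed = s, n = 60)
    net <- build_network(ds)
    seeds <- ds$indexes$index_id[ds$indexes$is_key_distributor == 1]
    res <- simulate_distribution(net, seeds,
                                 simulation_config(seed = s * 3))
    injected <- length(seeds) * 4
    expect_equal(res$kits_injected, injected)
    expect_equal(sum(res$kits_held), injected)
    expect_lte(nrow(res$transfers), injected)
    # every transfer follows an observed index-alter edge
    if (nrow(res$transfers) > 0) {
      key <- paste(ds$alters$index_id, ds$alters$alter_id)
      expect_true(all(paste(res$transfers$from, res$transfers$to) %in% key))
      # redistribution off: only index nodes distribute
      expect_true(all(res$transfers$from %in% ds$indexes$index_id))
    }
  }
})

test_that("efficiency is monotone in the seed set under common random numbers", {
  ds <- quick_dataset(seed = 77, n = 80)
  net <- build_network(ds)
  cand <- ds$indexes$index_id[ds$indexes$n_alters > 0]
  small <- cand[1:3]
  big <- cand[1:min(8, length(cand))]
  mean_eff <- function(seeds) {
    mean(vapply(1:50, function(r) {
      simulate_distribution(net, seeds,
                            simulation_config(seed = r))$efficiency
    }, numeric(1)))
  }
  expect_gte(mean_eff(big), mean_eff(small))
})

test_that("identical seeds give identical transfer logs", {
  ds <- quick_dataset(seed = 14, n = 50)
  net <- build_network(ds)
  seeds <- ds$indexes$index_id[ds$indexes$n_alters >= 1][1:4]
  r1 <- simulate_distribution(net, seeds, simulation_config(seed = 9))
  r2 <- simulate_distribution(net, seeds, simulation_config(seed = 9))
  expect_identical(r1$transfers, r2$transfers)
  expect_identical(r1$tested, r2$tested)
})

test_that("intervention efficiency is tested nodes over all nodes", {
  net <- star_network(4)
  res <- simulate_distribution(net, "I1", simulation_config(seed = 2))
  expect_equal(intervention_efficiency(res, net),
               round(100 * length(res$tested) / 5, 1))
  expect_error(intervention_efficiency(res, igraph::make_empty_graph()),
               "empty network")
})

test_that("strategy comparison: identical flags tie exactly, empty baseline scores zero", {
  ds <- quick_dataset(seed = 23, n = 75)
  folds <- fold_plan(ds$indexes$is_key_distributor, 5, seed = 1)
  flags <- ds$indexes$is_key_distributor
  cmp <- compare_strategies(ds, folds, flags, flags,
                            simulation_config(seed = 4), n_replicates = 3)
  expect_true(all(cmp$per_fold$diff == 0))

  none <- rep(0L, nrow(ds$indexes))
  cmp0 <- compare_strategies(ds, folds, flags, none,
                             simulation_config(seed = 4), n_replicates = 2)
  expect_true(all(cmp0$per_fold$baseline == 0))
})

test_that("true key distributors beat random same-size seed sets", {
  wins <- 0L; total <- 0L
  for (s in 1:10) {
    ds <- generate_trial(generator_config(n_indexes = 150, seed = 200 + s))
    flags <- ds$indexes$is_key_distributor
    k <- sum(flags)
    rand <- integer(length(flags))
    rand[withr::with_seed(s, sample(length(flags), k))] <- 1L
    folds <- fold_plan(flags, 5, seed = s)
    cmp <- compare_strategies(ds, folds, flags, rand,
                              simulation_config(seed = s),
                              n_replicates = 10)
    wins <- wins + sum(cmp$per_fold$diff >= 0)
    total <- total + nrow(cmp$per_fold)
  }
  # ML-like seeding dominates in at least 4 of 5 folds on average
  expect_gte(wins / total, 0.8)
})
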