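#' Build the bipartite index-alter distribution network
#'
#' One node per index and per alter; an edge links an alter to the index
#' whose kit (confirmation code) it received. Kits can only travel along
#' these observed edges in the diffusion simulation.
#'
#' @param indexes Index data frame (or a `trial_dataset`, in which case
#'   `alters` is taken from it).
#' @param alters Alter data frame with `alter_id` and `index_id`.
#' @return An [igraph][igraph::igraph-package] bipartite graph; index
#'   nodes have `type = FALSE`, alter nodes `type = TRUE`.
#' @export
build_network <- function(indexes, alters = NULL) {
  if (inherits(indexes, "trial_dataset")) {
    alters <- indexes$alters
    indexes <- indexes$indexes
  }
  bad <- setdiff(alters$index_id, indexes$index_id)
  if (length(bad) > 0L) {
    stop(sprintf("integrity error: edges reference unknown index id(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(c(indexes$index_id, alters$alter_id))) {
    stop("integrity error: duplicated node identifiers", call. = FALSE)
  }
  vertices <- data.frame(
    name = c(indexes$index_id, alters$alter_id),
    type = c(rep(FALSE, nrow(indexes)), rep(TRUE, nrow(alters))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = alters$index_id, to = alters$alter_id,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Configuration of the kit-diffusion simulation
#'
#' @param kits_per_seed Kits allocated to each seeded index (default 4,
#'   the programme allocation).
#' @param max_steps Step cap; the run also stops at the first step with
#'   no transfer.
#' @param redistribution Whether alters holding spare kits pass them on
#'   (default `FALSE`: the observed process is one hop, index to alter).
#' @param seed RNG seed of the simulation.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(kits_per_seed = 4L, max_steps = 10L,
                              redistribution = FALSE, seed = 1L) {
  if (!is.numeric(kits_per_seed) || kits_per_seed < 1) {
    stop_config("kits_per_seed", "must be >= 1")
  }
  if (!is.numeric(max_steps) || max_steps < 1) {
    stop_config("max_steps", "must be >= 1")
  }
  structure(list(kits_per_seed = as.integer(kits_per_seed),
                 max_steps = as.integer(max_steps),
                 redistribution = isTRUE(redistribution),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate secondary distribution of kits on the network
#'
#' Seeded indexes start with `kits_per_seed` kits, Poisson rate
#' \eqn{\lambda} equal to that allocation, and count as tested (they
#' keep a kit for themselves). At each time step every kit-holding node
#' eligible to distribute draws \eqn{d \sim \mathrm{Poisson}(\lambda)} —
#' the mean number of kits it wants to pass on — capped by the kits it
#' actually holds and by its unreached neighbors, and hands one kit each
#' to `d` distinct unreached neighbors chosen uniformly without
#' replacement. A receiver is marked tested and its \eqn{\lambda} is set
#' to the number of kits received. The run stops at the first step with
#' no transfer, or after `max_steps`.
#'
#' @param network Bipartite graph from [build_network()].
#' @param seeds Character vector of seeded index node names (may be
#'   empty).
#' @param config A [simulation_config()].
#' @return Object of class `simulation_result`: `tested` (node names),
#'   `transfers` (data frame `step`, `from`, `to`), `efficiency`
#'   (percent of all nodes tested), `kits_injected`, `kits_held` (final
#'   holdings by node).
#' @export
simulate_distribution <- function(network, seeds, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  nodes <- igraph::V(network)$name
  is_alter <- igraph::V(network)$type
  if (!all(seeds %in% nodes[!is_alter])) {
    stop(sprintf("validation error: unknown seed id(s): %s",
                 paste(head(setdiff(seeds, nodes[!is_alter]), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  n <- length(nodes)
  adj <- igraph::as_adj_list(network)
  adj <- lapply(adj, function(v) as.integer(v))
  kits <- integer(n)
  lambda <- numeric(n)
  tested <- logical(n)
  sidx <- match(seeds, nodes)
  kits[sidx] <- config$kits_per_seed
  lambda[sidx] <- config$kits_per_seed
  tested[sidx] <- TRUE
  log_step <- integer(0); log_from <- integer(0); log_to <- integer(0)

  withr::with_seed(child_seed(config$seed, 31L), {
    for (step in seq_len(config$max_steps)) {
      moved <- FALSE
      holders <- which(kits > 0L & tested &
                         (config$redistribution | !is_alter))
      for (h in holders) {
        nb <- adj[[h]]
        open <- nb[!tested[nb]]
        if (length(open) == 0L || kits[h] == 0L) next
        d <- rpois(1L, lambda[h])
        d <- min(d, kits[h], length(open))
        if (d == 0L) next
        to <- if (length(open) == 1L) open else sample(open, d)
        kits[h] <- kits[h] - d
        kits[to] <- kits[to] + 1L
        lambda[to] <- 1
        tested[to] <- TRUE
        moved <- TRUE
        log_step <- c(log_step, rep(step, d))
        log_from <- c(log_from, rep(h, d))
        log_to <- c(log_to, to)
      }
      if (!moved) break
    }
  })
  structure(
    list(tested = nodes[tested],
         transfers = data.frame(step = log_step, from = nodes[log_from],
                                to = nodes[log_to],
                                stringsAsFactors = FALSE),
         efficiency = if (n > 0L) 100 * sum(tested) / n else 0,
         kits_injected = length(sidx) * config$kits_per_seed,
         kits_held = setNames(kits, nodes)),
    class = "simulation_result"
  )
}

#' Intervention efficiency of a simulation run
#'
#' The percentage of all network individuals (indexes and alters) who
#' have self-tested when the simulation ends.
#'
#' @param result A `simulation_result`.
#' @param network The network it was produced on.
#' @return Percent, one decimal.
#' @export
intervention_efficiency <- function(result, network) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("validation error: empty network", call. = FALSE)
  round(100 * length(result$tested) / n, 1)
}

#' Compare two seeding strategies by simulated intervention efficiency
#'
#' For each cross-validation test fold, the fold's indexes and their
#' alters form the network; each strategy seeds the indexes it flags in
#' that fold, and efficiency is averaged over `n_replicates` simulation
#' repeats. Replicate RNG seeds depend only on the fold and replicate
#' (common random numbers), so identical flag sets give identical
#' results and differences between strategies are not inflated by
#' simulation noise.
#'
#' @param dataset A labeled `trial_dataset`.
#' @param folds Fold plan from [fold_plan()] (test index sets into
#'   `dataset$indexes`).
#' @param ml_flags,baseline_flags 0/1 vectors over all indexes (in
#'   `dataset$indexes` row order): which indexes each strategy seeds.
#' @param config A [simulation_config()].
#' @param n_replicates Simulation repeats per fold and strategy.
#' @return Object of class `strategy_comparison`: per-fold efficiencies
#'   of both strategies, their averages, per-fold differences and the
#'   [fold_diff_ci()] summary.
#' @export
compare_strategies <- function(dataset, folds, ml_flags, baseline_flags,
                               config = simulation_config(),
                               n_replicates = 20L) {
  idx <- dataset$indexes
  stopifnot(length(ml_flags) == nrow(idx),
            length(baseline_flags) == nrow(idx))
  ml_flags <- coerce_binary(ml_flags)
  baseline_flags <- coerce_binary(baseline_flags)
  eff <- matrix(NA_real_, nrow = length(folds), ncol = 2,
                dimnames = list(NULL, c("ml", "baseline")))
  for (j in seq_along(folds)) {
    rows <- folds[[j]]
    sub_idx <- idx[rows, , drop = FALSE]
    sub_alt <- dataset$alters[dataset$alters$index_id %in% sub_idx$index_id,
                              , drop = FALSE]
    net <- build_network(sub_idx, sub_alt)
    for (s in 1:2) {
      flags <- if (s == 1L) ml_flags else baseline_flags
      seeds <- sub_idx$index_id[flags[rows] == 1L]
      effs <- vapply(seq_len(n_replicates), function(r) {
        cfg <- config
        cfg$seed <- child_seed(config$seed, j, r)  # strategy-independent
        simulate_distribution(net, seeds, cfg)$efficiency
      }, numeric(1))
      eff[j, s] <- mean(effs)
    }
  }
  diffs <- eff[, "ml"] - eff[, "baseline"]
  structure(
    list(per_fold = data.frame(fold = seq_along(folds),
                               ml = eff[, "ml"],
                               baseline = eff[, "baseline"],
                               diff = diffs),
         average = c(ml = mean(eff[, "ml"]),
                     baseline = mean(eff[, "baseline"])),
         diff_ci = fold_diff_ci(diffs)),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf(
    "<strategy_comparison> ML %.1f%% vs baseline %.1f%% | diff %.1f (%.1f, %.1f)\n",
    x$average["ml"], x$average["baseline"], x$diff_ci["mean"],
    x$diff_ci["lower"], x$diff_ci["upper"]))
  invisible(x)
}
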