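---
title: "Methods: ensemble identification of key HIVST influencers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble identification of key HIVST influencers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivstkey)
```

# Scope and model

`hivstkey` studies whether a machine-learning system identifies better
*key influencers* for secondary distribution of HIV self-testing kits
than a self-reported leadership scale. An index participant is a key
**distributor** if they passed kits to at least 2 alters, a key
**promoter** if at least one alter was a first-time tester, a key
**detector** if at least one alter tested HIV-positive. Each rule is a
binary classification problem over the index participants' survey
covariates and their 6 leadership-scale items.

The identification system is deliberately simple and fully
deterministic given its seeds:

1. fit logistic regression (LR), a linear-kernel SVM, a CART tree (DT)
   and a random forest (RF) on all predictors;
2. rank predictors per family — LR by |standardized coefficient|, SVM
   by recursive feature elimination (refit, drop the predictor with the
   smallest squared primal weight, one per round; last survivor ranks
   first), DT/RF by total Gini-impurity decrease;
3. select the intersection of the four top-*k* ranking prefixes
   (*cross-model voting*), growing *k* until non-empty;
4. refit the four families on the selected predictors and combine them
   by *soft voting*: the ensemble class-1 probability is the weighted
   mean of member probabilities; the label is positive when it reaches
   the decision threshold.

## Parameter choices where the design was open

* **LR estimator.** Plain maximum-likelihood `glm`. An L2-penalized fit
  was considered and rejected: the standardized-coefficient importance
  rule and the package's own oracle test (the fitted log odds ratio of
  a single binary predictor must equal the closed-form 2×2 table value)
  are exact only without shrinkage, and at n ≈ 309 with ≤ ~16
  predictors separation is rare.
* **SVM probabilities.** Margin outputs are not probabilities; the SVM
  member uses Platt-type sigmoid calibration (fitted by `e1071` on
  internal cross-validation of the training fold) so it can vote
  softly. RFE refits skip calibration — only the weight vector is
  needed.
* **Voting prefix `top_k`.** Default `ceiling(p/3)`: with the default
  16 predictors that is 6, small enough to force consensus, and the
  auto-increment guarantees a non-empty selection in the worst case.
* **Ensemble weights** are equal (¼ each) and the **decision
  threshold** is 0.5 with ties classified positive. Both are
  configurable in `ensemble_config()`.
* **Tree/forest defaults.** Tree: minimum leaf 5, minimum split 10, no
  complexity pruning, depth cap 30. Forest: 100 trees. Intended as
  conventional fixed settings, not tuned values; there is no
  hyperparameter search anywhere.
* **Standardization.** Continuous predictors are z-scored on the
  training split only (the transform travels with the fitted model);
  0/1 columns pass through. This makes LR coefficients comparable and
  the SVM geometry scale-free, without leaking test-fold moments.
* **Missing values** fail fast by design; the generator never emits
  them.

# Evaluation

Stratified 5-fold cross-validation (indices shuffled within class and
dealt cyclically, so fold sizes differ by ≤ 1 and even the ~7%-positive
detector rule keeps positives in every fold). Predictor selection and
all fitting happen inside each training fold; test folds are untouched
by selection, a stricter protocol than selecting once on the full data.
Accuracy, precision, recall and F1 use the conservative
zero-denominator convention (undefined → 0). Fold averages are
unweighted means.

The leadership-scale baseline is evaluated on the same test folds. Its
two thresholds come from the *full* sample, as a programme would set
them: cutoff B is the largest score reaching the top-20% headcount,
cutoff A is one point higher. With the generator's default tie clump
the pair brackets the target headcount just as the real scale did.
Cutoff A is the default comparator because it produces the
headcount-matched set.

Two interval conventions coexist deliberately, because the published
comparisons use both:

* `wald_diff_ci()` — Wald difference of proportions with a shared
  denominator, `(p1−p2) ± 1.959964·√(p1(1−p1)/n + p2(1−p2)/n)`, for
  count comparisons (kits, first-time alters, positive alters);
* `fold_diff_ci()` — `mean ± 1.959964·SD_pop` over per-fold
  differences, with the population (n-denominator) SD, for
  cross-validation fold summaries.

The **increased percentage** uses the shared total as denominator
(`(146−97)/269`, not `/146`): it reads as "percentage points of the
achievable total gained", and is antisymmetric in the two strategies.
Percentages are reported to one decimal. A published "11.0% average
accuracy gain" analogue is recomputed, never asserted: the exact
averaging recipe behind that figure (which models, cutoffs and rules,
rounded or not) is ambiguous, so the package reports its own
`synthetic_accuracy_gain_pct` instead.

In `run_study()` the count and simulation comparisons are
**headcount-matched**: the machine set is the top `count_A` indexes by
out-of-fold ensemble probability (ties broken by index order), so both
strategies flag equally many people and neither gains by being more
liberal. This mirrors the published comparison, which was only
considered rational because both sets happened to contain 49 people.

# The diffusion simulator

The network is bipartite: one node per index and per alter, an edge
where a kit's confirmation code links them. Seeded indexes start with 4
kits (the programme allocation; orders rarely exceeded 5), Poisson rate
λ equal to that allocation, and count as tested. Each step, every
kit-holding distributor draws `d ~ Poisson(λ)` — the number of kits it
*wants* to pass on — and actually passes `min(d, kits held, unreached
neighbours)` kits, one each to uniformly chosen unreached neighbours; a
receiver is marked tested (receiving a kit is equated with self-testing
in the efficiency metric) and gets λ = kits received. The run stops at
the first step with no transfer or after `max_steps` (default 10).
Efficiency is the percentage of **all** fold-network nodes (indexes and
alters) tested at the end.

Choices worth flagging:

* The raw Poisson is uncapped; the caps are required for kit
  conservation (kits transferred can never exceed kits injected) and
  are a documented deviation from the idealized draw. A test checks
  the capped first-step mean against an exact enumeration oracle.
* `redistribution = FALSE` by default: the observed process is one hop
  (each alter has exactly one index edge), so alters sit on received
  kits. The flag exists because multi-step diffusion is a natural
  extension.
* Stopping at a transfer-free step means a quiescent early step can end
  a run with kits left; with λ = 4 this is rare (probability e⁻⁴ per
  holder) and mirrors a finite distribution window.
* Seeds are restricted to the fold's indexes so per-fold efficiencies
  are well defined, and replicate seeds depend only on (fold,
  replicate) — common random numbers across strategies, so identical
  seed sets give exactly identical results.

# The synthetic generator

Real index-level data are not public, so every pipeline stage runs on a
generator whose *defaults are the study conditions*:

* **Covariates** (schema configurable; the real survey's predictor list
  is not public, so this is a plausible stand-in): age, education,
  income, ever-tested, months since last test, partner count, app-use
  frequency, disclosure status, plus the randomization arm (SD /
  SD-M / SD-M-PR) as two dummies.
* **Propensity.** θ = logistic(b₀ + Σ βⱼ·z(xⱼ)) with planted signal in
  app use (0.9), partner count (0.7), ever-tested (0.5), education
  (0.3) and a small negative weight on months-since-last-test; the
  rest are noise predictors.
* **Alter counts.** Zero-inflated Poisson with rate 2μθᵢ. 80% of real
  indexes distributed ≤ 1 kit while 60 distributors accounted for >70%
  of alters, implying strong overdispersion; the propensity
  heterogeneity supplies it. (π₀ = 0.0532, μ = 13.007, b₀ = −4.0325)
  were calibrated numerically — three parameters to three moments:
  mean alters 269/309, P(N = 1) ≈ 0.21, P(N ≥ 2) = 60/309. The
  promoter/detector/first-time/positive marginals then *emerge* from
  the alter-level flag rates 103/269 and 25/269; an acceptance test
  confirms all six expected marginals stay within 15% of the published
  counts over 200 seeds.
* **Scale items.** A latent leader trait mixes the standardized
  propensity (weight `scale_signal`, default 0.5) with noise; each
  item loads 0.45 on the trait and is discretized to 0–4 at fixed
  Gaussian cutpoints with marginal probabilities (.40, .27, .18, .10,
  .05). This yields integer totals that clump just above the 80th
  percentile — reproducing, in spirit, the tie structure that forces
  the dual cutoffs — and a scale that is informative but strictly
  weaker than the covariate signal, as a self-report proxy should be.
* **Determinism.** One seed; every phase (covariates, counts, flags,
  items, folds, each simulation replicate) consumes a derived child
  seed, so datasets are byte-identical across runs and no global RNG
  state is touched.

What the generator does **not** emulate: the real predictor marginals
and their correlations (unpublished), arm effects on distribution
(retained only as a covariate), within-network correlation of alter
outcomes (flags are independent Bernoulli), and recruitment dynamics.
Passing tests therefore demonstrate that the *method pipeline* behaves
correctly and that the machine-vs-scale ordering holds under these
assumptions — not that the real trial's accuracy table is recovered.

# Problem sizes and numerical conventions

The test suite works at deliberately modest sizes: structural tests on
80–150-index datasets, planted-predictor recovery at n = 2000 with 20
Monte-Carlo repetitions, generator calibration over 200 seeds at the
full 309-index scale, and the ensemble-vs-cutoff comparison over 10
full-scale replicates. Probability comparisons use exact arithmetic
(the soft vote is a matrix product; an oracle test requires agreement
to 1e-12); reported percentages are rounded to one decimal, matching
the published display precision, and metric tables to two.

# Limitations

The ensemble's absolute performance on real trial data cannot be
validated here; only the published derived statistics are exactly
reproducible (and are, via `selftest_printed_arithmetic()`). The
SVM-RFE ranking refits one model per predictor and dominates runtime
for wide feature tables. The simulator equates receiving a kit with
testing and ignores behavioural heterogeneity beyond the Poisson rate.
At detector-rule prevalence (~7%), threshold-0.5 classifiers often
predict the majority class; precision/recall in the report make this
visible, and headcount-matched comparisons (rather than raw flags) are
the fair basis for strategy contrasts.
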