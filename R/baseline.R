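#' Score the six-item self-reported leadership scale
#'
#' Each of the 6 social-influence items is self-rated 0-4; the scale
#' score is their simple sum, ranging 0-24.
#'
#' @param items Integer vector of length 6 (or a matrix/data frame with 6
#'   columns, one row per index), each entry in 0..4.
#' @return The total score(s).
#' @examples
#' score_scale(c(1, 2, 3, 0, 4, 1))  # 11
#' @export
score_scale <- function(items) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1L) else as.matrix(items)
  if (ncol(m) != 6L) {
    stop("validation error: the leadership scale has exactly 6 items",
         call. = FALSE)
  }
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0) || any(m > 4)) {
    stop("validation error: each scale item must be an integer in 0..4",
         call. = FALSE)
  }
  tot <- as.integer(rowSums(m))
  if (is.null(dim(items))) tot[1] else tot
}

#' Rank-order cutoffs of the leadership scale around a target fraction
#'
#' The human-identification baseline flags the top `target_fraction`
#' (default 20%) of indexes by scale score. Because integer totals tie,
#' the exact target headcount is usually not achievable: this returns the
#' two bracketing thresholds. Cutoff B is the largest score `s` such that
#' at least `target_count` indexes score `>= s` (so it flags
#' `count_B >= target_count` indexes); cutoff A is `s + 1` (flagging
#' `count_A <= target_count`).
#'
#' @param scores Integer vector of scale totals.
#' @param target_fraction Fraction of indexes to target, in (0, 1).
#' @return An object of class `cutoff_pair`: list with `target_count`,
#'   `threshold_A`, `count_A`, `threshold_B`, `count_B`.
#' @export
find_cutoffs <- function(scores, target_fraction = 0.2) {
  if (length(scores) == 0L) {
    stop("validation error: empty score list", call. = FALSE)
  }
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1) {
    stop("validation error: target_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- length(scores)
  target_count <- round(target_fraction * n)
  # counts of {score >= s} are non-increasing in s; threshold_B is the
  # largest s still reaching the target headcount
  cand <- sort(unique(c(scores, max(scores) + 1L)), decreasing = TRUE)
  counts <- vapply(cand, function(s) sum(scores >= s), integer(1))
  ok <- counts >= target_count
  threshold_B <- if (any(ok)) cand[which(ok)[1]] else min(scores)
  threshold_A <- threshold_B + 1L
  structure(
    list(target_count = target_count,
         threshold_A = as.integer(threshold_A),
         count_A = sum(scores >= threshold_A),
         threshold_B = as.integer(threshold_B),
         count_B = sum(scores >= threshold_B)),
    class = "cutoff_pair"
  )
}

#' @export
print.cutoff_pair <- function(x, ...) {
  cat(sprintf(
    "<cutoff_pair> target %d | A: >=%d flags %d | B: >=%d flags %d\n",
    x$target_count, x$threshold_A, x$count_A, x$threshold_B, x$count_B))
  invisible(x)
}

#' Classify indexes with a leadership-scale cutoff
#'
#' @param scores Integer vector of scale totals.
#' @param cutoffs A `cutoff_pair` from [find_cutoffs()].
#' @param which Which cutoff to apply, `"A"` (stricter) or `"B"`
#'   (more inclusive).
#' @return Integer 0/1 flags, 1 when `score >= threshold`.
#' @export
baseline_classify <- function(scores, cutoffs, which = c("A", "B")) {
  which <- match.arg(which)
  stopifnot(inherits(cutoffs, "cutoff_pair"))
  thr <- if (which == "A") cutoffs$threshold_A else cutoffs$threshold_B
  as.integer(scores >= thr)
}
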