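#' P-value truncation threshold grid
#'
#' Candidate truncation thresholds for the adaptive combination. The
#' default is the 11-point grid 0.10, 0.11, ..., 0.20; the wider 21-point
#' alternative 0.05, ..., 0.25 gives very similar results at extra cost.
#'
#' @param start,stop,step grid specification, strictly inside (0, 1)
#' @return increasing numeric vector of class `threshold_grid`
#' @export
threshold_grid <- function(start = 0.10, stop = 0.20, step = 0.01) {
  thetas <- seq(start, stop, by = step)
  stopifnot(length(thetas) >= 1, all(diff(thetas) > 0) || length(thetas) == 1,
            thetas[1] > 0, thetas[length(thetas)] < 1)
  structure(thetas, class = "threshold_grid")
}

#' Truncated weighted Fisher significance scores
#'
#' For each truncation threshold `theta_j` the significance score sums the
#' weighted Fisher contributions of the variants whose P-values pass the
#' threshold:
#' \deqn{S_j = \sum_l w_l \, (-\ln p_l) \, I[p_l \le \theta_j].}
#' Larger variants' P-values are truncated away so that neutral variants do
#' not dilute the region signal; which threshold is best is settled later
#' by permutation. `S_j` is non-decreasing in `theta_j` and zero when no
#' P-value passes.
#'
#' @param pvals per-variant P-values in (0, 1]; exact zeros are clamped to
#'   the smallest positive double with a warning
#' @param weights non-negative per-variant weights ([maf_weights()] or
#'   [pc_weights()])
#' @param grid a [threshold_grid()]
#' @return numeric vector `S_j`, one per threshold
#' @export
significance_scores <- function(pvals, weights, grid = threshold_grid()) {
  stopifnot(length(pvals) == length(weights))
  if (any(pvals <= 0)) {
    warning("P-values of 0 clamped to the smallest positive double")
    pvals <- pmax(pvals, .Machine$double.xmin)
  }
  contrib <- as.numeric(weights) * (-log(pvals))
  vapply(as.numeric(grid),
         function(theta) sum(contrib[pvals <= theta]), numeric(1))
}

#' Rank P-values of significance scores across the permutation pool
#'
#' `S` has `B + 1` rows (row 1 = the observed sample, rows 2..B+1 =
#' permutations) and one column per threshold. Every row is ranked within
#' its column against the whole pool, counting itself and ties inclusively,
#' so each P lies in `[1/(B+1), 1]` and the observed row's P equals
#' `(1 + #{b : S_j^(b) >= S_j}) / (B + 1)`.
#'
#' @param S significance-score matrix, samples by thresholds
#' @return matrix of rank P-values, same shape
#' @export
rank_pvalues <- function(S) {
  S <- as.matrix(S)
  N <- nrow(S)
  stopifnot(N >= 2)
  apply(S, 2, function(col) (N - rank(col, ties.method = "min") + 1) / N)
}

#' Minimum rank P-value per sample
#'
#' Row-wise minimum of the per-threshold rank P-values; the permutation
#' distribution of this minimum yields the threshold-adjusted P-value.
#'
#' @param P matrix of rank P-values, samples by thresholds
#' @return numeric vector, one MinP per row
#' @export
min_p <- function(P) {
  P <- as.matrix(P)
  do.call(pmin, as.data.frame(P))
}

#' Permutation-adjusted P-value
#'
#' Monte Carlo P-value of the observed MinP against the permuted MinP
#' values, with the add-one convention that guarantees a positive estimate:
#' `(1 + #{b : MinP^(b) <= MinP_obs}) / (B + 1)`.
#'
#' @param minp_obs observed MinP
#' @param minp_perms vector of B permutation MinP values
#' @return adjusted P-value in `[1/(B+1), 1]`
#' @export
adjusted_pvalue <- function(minp_obs, minp_perms) {
  B <- length(minp_perms)
  stopifnot(B >= 1)
  (1 + sum(minp_perms <= minp_obs)) / (B + 1)
}
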