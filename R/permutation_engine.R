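#' Sequential Monte Carlo configuration
#'
#' Controls the permutation loop of [run_conada()]. Sampling never stops
#' before `bmin` permutations, always stops at `bmax`, and stops early once
#' the number of permuted MinP values at or below the observed MinP reaches
#' the exceedance target `h = ceiling(1 / c^2)` (16 at the default
#' `c = 0.25`), at which point the relative standard error of the adjusted
#' P-value is approximately `c`.
#'
#' @param bmin,bmax minimum / maximum permutation counts (defaults 100 and
#'   10000)
#' @param c target relative standard error of the adjusted P-value
#'   (default 0.25)
#' @param batch permutations per batch between stopping checks
#' @param seed optional integer seed applied by [run_conada()]
#' @return list of class `sequential_config`
#' @export
sequential_config <- function(bmin = 100, bmax = 10000, c = 0.25,
                              batch = 100, seed = NULL) {
  stopifnot(bmin >= 1, bmin <= bmax, c > 0, c < 1, batch >= 1)
  structure(list(bmin = bmin, bmax = bmax, c = c,
                 h = ceiling(1 / c^2), batch = batch, seed = seed),
            class = "sequential_config")
}

#' Flip a child to the non-transmitted diplotype
#'
#' Under the no-recombination assumption each parental haplotype acts as a
#' single allele, so the null permutation swaps the child's observed
#' diplotype for the two originally non-transmitted haplotypes. At the
#' genotype-score level the flipped child score at every locus is
#' `f + m - c`; missing trio-loci stay missing. The flip is applied jointly
#' across loci (one haplotype-pair swap per trio) and is an involution.
#'
#' @param father,mother,child genotype-score vectors of one trio
#' @return flipped child score vector
#' @export
flip_child <- function(father, mother, child) {
  flipped <- father + mother - child
  bad <- !is.na(flipped) & (flipped < 0 | flipped > 2)
  if (any(bad)) {
    stop("Mendelian-incompatible trio at locus ", which(bad)[1],
         "; screen with check_mendelian() first")
  }
  flipped
}

#' Permute a dataset by fair-coin transmission flipping
#'
#' Each trio's child is independently replaced by its non-transmitted
#' diplotype with probability 1/2 (see [flip_child()]); parents and
#' controls are untouched, so per-variant weights and conditional
#' expectations are identical across permutations.
#'
#' @param ds a [region_dataset()]
#' @param coins optional 0/1 vector of length `n_trios(ds)` overriding the
#'   coin tosses (1 = flip)
#' @return the permuted [region_dataset()]
#' @export
permute_dataset <- function(ds, coins = NULL) {
  n <- n_trios(ds)
  if (is.null(coins)) coins <- stats::rbinom(n, 1L, 0.5)
  stopifnot(length(coins) == n, all(coins %in% 0:1))
  flip <- coins == 1L
  if (any(flip)) {
    flipped <- ds$father[flip, , drop = FALSE] +
      ds$mother[flip, , drop = FALSE] - ds$child[flip, , drop = FALSE]
    if (any(!is.na(flipped) & (flipped < 0L | flipped > 2L))) {
      stop("Mendelian-incompatible trio-locus; screen with check_mendelian()")
    }
    ds$child[flip, ] <- flipped
  }
  ds
}

# Sufficient statistics for fast permutation scoring.  Only the child
# scores change under flipping, and flipping trio i negates its deviation
# delta_i = c_i - (f_i + m_i)/2, so the permuted numerator at each variant
# is d - 2 * coins %*% Delta.  Variances and weights never change.
.perm_kernel <- function(ds) {
  ok <- .trio_complete(ds)
  dev <- ds$child - (ds$father + ds$mother) / 2
  dev[!ok] <- 0
  var_ <- conditional_variance(ds$father, ds$mother)
  var_[!ok] <- 0
  list(Delta = dev, d = colSums(dev), v = colSums(var_))
}

# Coin matrix (B x n) -> significance-score matrix (B x J).
.scores_for_coins <- function(kern, coins, weights, grid) {
  Dp <- matrix(kern$d, nrow(coins), length(kern$d), byrow = TRUE) -
    2 * (coins %*% kern$Delta)
  P <- matrix(1, nrow(Dp), ncol(Dp))
  pos <- kern$v > 0
  if (any(pos)) {
    P[, pos] <- stats::pchisq(
      sweep(Dp[, pos, drop = FALSE]^2, 2, kern$v[pos], `/`),
      df = 1, lower.tail = FALSE)
  }
  contrib <- sweep(-log(pmax(P, .Machine$double.xmin)), 2,
                   as.numeric(weights), `*`)
  vapply(as.numeric(grid),
         function(theta) rowSums(contrib * (P <= theta)), numeric(nrow(P)))
}

#' Exact null distribution by full enumeration
#'
#' Evaluates the significance scores and MinP for every one of the `2^n`
#' transmission-flip patterns of an `n`-trio dataset (feasible for
#' `n <= 20`). The exact threshold-adjusted P-value of the observed data is
#' its inclusive rank: the proportion of patterns whose MinP is at or below
#' the observed MinP. This is the oracle against which the Monte Carlo
#' permutation P-value is validated.
#'
#' @param ds a [region_dataset()] with at most 20 trios
#' @param weights per-variant weights
#' @param grid a [threshold_grid()]
#' @return list with the score matrix `S` (`2^n` rows, observed pattern
#'   first), rank P-value matrix `P`, `MinP` vector and
#'   `exact_adjusted_p`
#' @export
enumerate_null <- function(ds, weights, grid = threshold_grid()) {
  n <- n_trios(ds)
  if (n > 20) stop("enumeration infeasible for n > 20 trios")
  kern <- .perm_kernel(ds)
  ids <- 0:(2^n - 1)
  coins <- vapply(0:(n - 1),
                  function(b) bitwAnd(bitwShiftR(ids, b), 1L),
                  integer(length(ids)))
  S <- .scores_for_coins(kern, coins, weights, grid)
  P <- rank_pvalues(S)
  minp <- min_p(P)
  list(S = S, P = P, MinP = minp,
       exact_adjusted_p = mean(minp <= minp[1]))
}

#' Run the conditioning adaptive combination of P-values test
#'
#' The full region test: per-variant conditional transmission P-values are
#' combined into truncated weighted Fisher significance scores over the
#' threshold grid; the per-threshold scores are converted to rank P-values
#' against transmission-flip permutations; the minimum rank P-value (MinP)
#' across thresholds is adjusted for the threshold search by comparing it
#' with the permuted MinP values. Permutations are drawn in batches under a
#' sequential Monte Carlo rule: after each batch beyond `bmin` the
#' exceedance count `#\{b : MinP^{(b)} <= MinP_obs\}` is checked against the
#' target `h`; on early stopping the adjusted P-value is the
#' Besag-Clifford estimate `h / B*` with `B*` the permutation at which the
#' h-th exceedance occurred, otherwise the add-one estimate
#' `(1 + count) / (1 + bmax)`.
#'
#' @param ds a [region_dataset()]; `mode = "PC"` requires controls
#' @param mode weighting scheme: `"PC"` (population-control trend weights)
#'   or `"MAF"` (Beta(1, 25) density weights from parental MAF)
#' @param grid a [threshold_grid()]
#' @param cfg a [sequential_config()]
#' @param seed integer seed for the permutation stream (overrides
#'   `cfg$seed`)
#' @return object of class `conada_result`: `adjusted_p`, `B_used`,
#'   `stopped_early`, `per_threshold` (theta, S_j, rank p_j),
#'   `per_variant` (variant_id, chrom, pos, T_l, p_l, w_l), `mode`, `seed`
#' @export
run_conada <- function(ds, mode = c("PC", "MAF"), grid = threshold_grid(),
                       cfg = sequential_config(), seed = cfg$seed) {
  mode <- match.arg(mode)
  if (mode == "PC" && is.null(ds$controls)) {
    stop("PC weighting requires controls; use mode = \"MAF\" for trio-only data")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- .compute_weights(ds, mode)
  kern <- .perm_kernel(ds)
  n <- n_trios(ds)

  p_obs <- .pvalues_from_summary(kern$d, kern$v)
  t_obs <- ifelse(kern$v > 0, kern$d^2 / kern$v, 0)
  S_obs <- significance_scores(p_obs, w, grid)

  S_all <- matrix(S_obs, nrow = 1)
  B <- 0L
  adjusted <- NA_real_
  stopped_early <- FALSE
  repeat {
    nb <- min(cfg$batch, cfg$bmax - B)
    coins <- matrix(stats::rbinom(nb * n, 1L, 0.5), nrow = nb, byrow = TRUE)
    S_all <- rbind(S_all, .scores_for_coins(kern, coins, w, grid))
    B <- B + nb
    if (B >= cfg$bmin) {
      minp <- min_p(rank_pvalues(S_all))
      count <- sum(minp[-1] <= minp[1])
      if (count >= cfg$h && B < cfg$bmax) {
        b_star <- which(minp[-1] <= minp[1])[cfg$h]
        adjusted <- cfg$h / b_star
        stopped_early <- TRUE
        break
      }
      if (B >= cfg$bmax) {
        adjusted <- (1 + count) / (1 + B)
        break
      }
    }
  }

  minp <- min_p(rank_pvalues(S_all))
  structure(list(
    adjusted_p = adjusted,
    B_used = B,
    stopped_early = stopped_early,
    per_threshold = data.frame(theta = as.numeric(grid), S_j = S_obs,
                               p_j = rank_pvalues(S_all)[1, ]),
    per_variant = data.frame(variant_id = ds$variants$variant_id,
                             chrom = ds$variants$chrom,
                             pos = ds$variants$pos,
                             T_l = t_obs, p_l = p_obs, w_l = as.numeric(w),
                             stringsAsFactors = FALSE),
    min_p_obs = minp[1],
    mode = mode,
    seed = if (is.null(seed)) NA_integer_ else seed
  ), class = "conada_result")
}

#' @export
print.conada_result <- function(x, ...) {
  cat(sprintf("conADA(%s): adjusted P = %.4g (B = %d%s)\n", x$mode,
              x$adjusted_p, x$B_used,
              if (x$stopped_early) ", early stop" else ""))
  invisible(x)
}
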