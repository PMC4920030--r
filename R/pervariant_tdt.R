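#' Expected offspring score given parental genotypes
#'
#' Under Mendelian transmission each parent passes the minor allele with
#' probability `g/2` where `g` is the parent's score, so the expected child
#' score is `(f + m) / 2`.
#'
#' @param f,m parental genotype scores in `{0, 1, 2}` (vectors recycle);
#'   `NA` propagates.
#' @return numeric expected child score
#' @export
expected_score <- function(f, m) (f + m) / 2

#' Conditional variance of the offspring score
#'
#' Only heterozygous parents are informative: each contributes variance
#' 1/4 to the child's score, homozygous parents contribute 0. Closed form
#' `f(2 - f)/4 + m(2 - m)/4`.
#'
#' @inheritParams expected_score
#' @return numeric conditional variance
#' @export
conditional_variance <- function(f, m) f * (2 - f) / 4 + m * (2 - m) / 4

# Per-variant transmission summary over trios with complete data at each
# locus: numerator d_l = sum_i (c_il - e_il), variance v_l = sum_i v_il,
# and the informative-heterozygous-parent count h_l (v_l = h_l / 4).
transmission_summary <- function(ds) {
  ok <- .trio_complete(ds)
  f <- ds$father; m <- ds$mother; c_ <- ds$child
  dev <- (c_ - (f + m) / 2); dev[!ok] <- 0
  var_ <- conditional_variance(f, m); var_[!ok] <- 0
  het <- (f == 1) + (m == 1); het[!ok] <- 0
  list(d = colSums(dev), v = colSums(var_), h = colSums(het),
       n_used = colSums(ok))
}

#' Per-variant conditional score statistic
#'
#' The transmission statistic at variant `l` is
#' \deqn{T_l = \left[\sum_i (c_{il} - e_{il})\right]^2 \big/ \sum_i
#'   \mathrm{Var}(c_{il} \mid f_{il}, m_{il}),}
#' the score test conditional on parental genotypes. Restricted to
#' heterozygous-parent transmissions it reduces to the classic TDT
#' \eqn{(b - c)^2 / (b + c)}; under the null it is asymptotically
#' chi-squared with 1 degree of freedom. Loci with no informative parent
#' (zero conditional variance) return 0.
#'
#' @param ds a [region_dataset()]
#' @param l variant index in `1..L`; omit for all variants
#' @return numeric vector of statistics
#' @export
variant_statistic <- function(ds, l = NULL) {
  ts <- transmission_summary(ds)
  t_all <- ifelse(ts$v > 0, ts$d^2 / ts$v, 0)
  if (is.null(l)) t_all else t_all[l]
}

#' Per-variant asymptotic P-values
#'
#' Upper-tail chi-squared(1) probability of [variant_statistic()] at each
#' variant; loci with zero conditional variance get P = 1 so that the
#' vector stays aligned with the weight vector across permutations.
#'
#' @param ds a [region_dataset()]
#' @return numeric vector of P-values in (0, 1]
#' @export
variant_pvalues <- function(ds) {
  ts <- transmission_summary(ds)
  .pvalues_from_summary(ts$d, ts$v)
}

.pvalues_from_summary <- function(d, v) {
  p <- rep(1, length(d))
  pos <- v > 0
  p[pos] <- stats::pchisq(d[pos]^2 / v[pos], df = 1, lower.tail = FALSE)
  p
}
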