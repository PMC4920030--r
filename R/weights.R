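#' Minor-allele frequency from parental genotypes
#'
#' Frequency of the counted allele among the `4 n_l` parental alleles at
#' each variant, where `n_l` is the number of trios fully observed at
#' variant `l`. This is the frequency the MAF weighting scheme uses; it is
#' a function of parents only and therefore invariant under transmission
#' permutation.
#'
#' @param ds a [region_dataset()]
#' @return numeric vector of frequencies in `[0, 1]`
#' @export
parental_maf <- function(ds) {
  ok <- .trio_complete(ds)
  f <- ds$father; m <- ds$mother
  f[!ok] <- 0L; m[!ok] <- 0L
  n_l <- colSums(ok)
  if (any(n_l == 0)) {
    warning("all trios missing at ", sum(n_l == 0),
            " variant(s); their MAF is set to 0")
  }
  maf <- ifelse(n_l > 0, (colSums(f) + colSums(m)) / (4 * n_l), 0)
  unname(maf)
}

#' Beta(1, 25) density weights from MAF
#'
#' The default rare-variant weighting scheme shared by SKAT, SKAT-O,
#' pedgene and the MAF-weighted rvTDT tests: the weight of a variant with
#' frequency `q` is the Beta(1, 25) density `25 (1 - q)^24`, which
#' up-weights the rarest variants (weight 25 at q = 0, vanishing at q = 1).
#'
#' @param maf numeric vector of frequencies in `[0, 1]`
#' @return object of class `weight_vector` (numeric with a `scheme`
#'   attribute, here `"MAF"`)
#' @export
maf_weights <- function(maf) {
  stopifnot(all(maf >= 0 & maf <= 1))
  structure(stats::dbeta(maf, 1, 25), scheme = "MAF", class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector (%s scheme), L = %d\n", attr(x, "scheme"),
              length(x)))
  print(unclass(x)[seq_len(min(10, length(x)))])
  invisible(x)
}

#' Genotype counts of trio parents versus population controls
#'
#' The 2 x 3 contingency table at one variant: control counts
#' `(r0, r1, r2)` and trio-parent counts `(s0, s1, s2)` by genotype score,
#' with margins. Each parent is counted once per trio (a parent appearing
#' in two trios is counted twice); missing genotypes are excluded.
#'
#' @param ds a [region_dataset()] with controls
#' @param l variant index
#' @return list with vectors `r`, `s` (length 3, genotypes 0/1/2) and
#'   margins `N_r`, `N_s`, `N_g` (column totals), `N`
#' @export
genotype_counts <- function(ds, l) {
  if (is.null(ds$controls)) stop("PC weighting requires controls")
  s <- tabulate(c(ds$father[, l], ds$mother[, l]) + 1L, nbins = 3L)
  r <- tabulate(ds$controls[, l] + 1L, nbins = 3L)
  list(r = r, s = s, N_r = sum(r), N_s = sum(s), N_g = r + s,
       N = sum(r) + sum(s))
}

#' Population-control trend weights
#'
#' Weighting scheme for conADA(PC): the weight of variant `l` is the
#' Cochran-Armitage trend chi-square statistic comparing the genotype
#' distribution of trio parents against population controls with scores
#' (0, 1, 2). The weight is large exactly when the two genotype
#' distributions differ, letting population controls up-weight variants
#' whose frequency separates the two samples. With `form = "z"` the square
#' root of the statistic is used instead; rank-based inference downstream
#' is invariant to any monotone rescaling applied to all weights, but the
#' two forms weight variants differently relative to each other.
#'
#' Closed form with `A = s1 + 2 s2`, `B = N1 + 2 N2`, `C = N1 + 4 N2`
#' (genotype-column margins `N_g`):
#' \deqn{w = N (N A - N_s B)^2 / [N_s (N - N_s)(N C - B^2)]}
#' and `w = 0` when the denominator vanishes (pooled-monomorphic variant).
#'
#' @param ds a [region_dataset()] with controls
#' @param form `"chisq"` (default) or `"z"`
#' @return a `weight_vector` with scheme `"PC"`
#' @export
pc_weights <- function(ds, form = c("chisq", "z")) {
  form <- match.arg(form)
  L <- n_variants(ds)
  w <- vapply(seq_len(L), function(l) {
    tb <- genotype_counts(ds, l)
    A <- tb$s[2] + 2 * tb$s[3]
    B <- tb$N_g[2] + 2 * tb$N_g[3]
    C <- tb$N_g[2] + 4 * tb$N_g[3]
    den <- tb$N_s * (tb$N - tb$N_s) * (tb$N * C - B^2)
    if (den <= 0) return(0)
    tb$N * (tb$N * A - tb$N_s * B)^2 / den
  }, numeric(1))
  if (form == "z") w <- sqrt(w)
  structure(w, scheme = "PC", class = "weight_vector")
}

# Weight dispatcher used by run_conada: weights depend only on parents and
# controls, so they are computed once and reused across permutations.
.compute_weights <- function(ds, mode) {
  switch(mode,
         MAF = maf_weights(parental_maf(ds)),
         PC = pc_weights(ds),
         stop("unknown weighting mode: ", mode))
}
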