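# Shared fixture builders: everything is generated in code at test time.

# Quick dataset from score matrices (vectors become 1-column matrices).
make_ds <- function(f, m, c, controls = NULL, ids = NULL) {
  f <- rbind(f); m <- rbind(m); c <- rbind(c)
  L <- ncol(c)
  variants <- data.frame(variant_id = paste0("v", seq_len(L)),
                         chrom = "1", pos = seq_len(L),
                         minor_allele = "A", stringsAsFactors = FALSE)
  if (!is.null(ids)) rownames(f) <- rownames(m) <- rownames(c) <- ids
  region_dataset(variants, f, m, c, controls)
}

# Random Mendelian-consistent trio dataset: parents are binomial(2, maf)
# draws, each parent transmits one allele at random.
random_trio_dataset <- function(n, L, maf = 0.3, controls = 0,
                                control_maf = maf) {
  f <- matrix(rbinom(n * L, 2L, maf), n, L)
  m <- matrix(rbinom(n * L, 2L, maf), n, L)
  transmit <- function(g) {        # allele count passed on by one parent
    (g == 2L) + (g == 1L) * rbinom(length(g), 1L, 0.5)
  }
  c_ <- matrix(transmit(f) + transmit(m), n, L)
  ctrl <- if (controls > 0) {
    matrix(rbinom(controls * L, 2L, control_maf), controls, L)
  } else NULL
  make_ds(f, m, c_, controls = ctrl)
}

# Direct transmitted/untransmitted tally of the classic TDT
# (b - c)^2 / (b + c) over heterozygous parents, used as the independent
# oracle for the per-variant statistic.
classic_tdt <- function(ds) {
  L <- n_variants(ds)
  vapply(seq_len(L), function(l) {
    f <- ds$father[, l]; m <- ds$mother[, l]; c_ <- ds$child[, l]
    ok <- !is.na(f) & !is.na(m) & !is.na(c_)
    b <- 0; cc <- 0                # transmitted / untransmitted minor
    for (i in which(ok)) {
      if (f[i] == 1 && m[i] == 1) {
        # both het: the child score counts the transmitted minor alleles;
        # a het child got one of each, order irrelevant for the totals
        b <- b + c_[i]; cc <- cc + (2 - c_[i])
      } else if (f[i] == 1 || m[i] == 1) {
        hom <- if (f[i] == 1) m[i] else f[i]
        t_het <- c_[i] - hom / 2   # allele from the het parent
        b <- b + t_het; cc <- cc + (1 - t_het)
      }
    }
    if (b + cc == 0) 0 else (b - cc)^2 / (b + cc)
  }, numeric(1))
}
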