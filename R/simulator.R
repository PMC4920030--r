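#' Two-subpopulation founder haplotype model
#'
#' Describes the region's variant panel and the two source subpopulations
#' ("EUR-like", with higher disease prevalence, and "AFR-like") from which
#' founder haplotype pools are built. Ancestral allele frequencies are
#' drawn from a Beta distribution truncated to a rare-variant range, and
#' the two subpopulations' frequencies diverge around them by a
#' Balding-Nichols construction with differentiation `fst`. Sampling
#' individuals from finite pools of `pool_size` haplotypes induces
#' within-region linkage disequilibrium; the pools stand in for
#' coalescent-simulated haplotypes with real LD patterns.
#'
#' @param L number of variant sites
#' @param fst differentiation between the subpopulations, in `[0, 1)`
#'   (default 0.1, of the order of continental human differentiation)
#' @param pool_size haplotypes per subpopulation pool (default 10000,
#'   matching a 10,000-haplotype source population per group)
#' @param freq_shape shape parameters of the ancestral-frequency Beta
#'   distribution (default `c(0.15, 2)`, a rare-skewed spectrum)
#' @param freq_max ancestral frequencies are truncated to
#'   `(0, freq_max]` (default 0.05)
#' @return list of class `population_model`
#' @export
population_model <- function(L = 87, fst = 0.1, pool_size = 10000,
                             freq_shape = c(0.15, 2), freq_max = 0.05) {
  stopifnot(L >= 1, fst >= 0, fst < 1, pool_size >= 2, freq_max > 0,
            freq_max <= 1)
  structure(list(L = L, fst = fst, pool_size = pool_size,
                 freq_shape = freq_shape, freq_max = freq_max),
            class = "population_model")
}

#' Disease model for the simulated study
#'
#' Logistic penetrance: a subject from subpopulation `s` with genotype
#' score vector `G` is affected with probability
#' `expit(beta0_s + beta . G)`, where `beta0_s = logit(K_s)` fixes the
#' baseline prevalence of the subpopulation and `beta` carries the
#' causal-variant effects (zero at neutral loci).
#'
#' @param prevalence named vector of subpopulation prevalences
#'   (default `c(EUR = 0.05, AFR = 0.01)`)
#' @param beta per-variant log-relative-risk vector (from
#'   [paf_to_beta()]; negative entries are protective)
#' @param causal integer indices of the causal loci
#' @return list of class `disease_model` with `beta0 = qlogis(prevalence)`
#' @export
disease_model <- function(prevalence = c(EUR = 0.05, AFR = 0.01),
                          beta = numeric(), causal = integer()) {
  stopifnot(all(prevalence > 0 & prevalence < 1))
  structure(list(prevalence = prevalence, beta0 = stats::qlogis(prevalence),
                 beta = beta, causal = causal),
            class = "disease_model")
}

#' Study design for the simulated trio + control experiment
#'
#' The sampling frame of one replicate study: how many ascertained
#' affected-child trios and unrelated controls, the subpopulation mixture
#' each is drawn from, which fraction of the rare loci (pooled founder
#' MAF at or below `causal_maf_cap`) is causal, the fraction of causal
#' loci that is deleterious (the rest protective), the per-locus
#' population attributable fraction `eta` that calibrates effect sizes,
#' and the analysis marker cap `max_maf`.
#'
#' @param n_trios number of case-parent trios (default 500)
#' @param n_controls number of unrelated controls (0 for trio-only)
#' @param trio_mix,control_mix length-2 EUR:AFR mixture proportions
#' @param causal_fraction fraction of rare loci that is causal (0 = null)
#' @param deleterious_fraction fraction of causal loci with positive
#'   effect
#' @param eta per-locus population attributable fraction
#' @param causal_maf_cap pooled-MAF cap defining the rare loci eligible to
#'   be causal (default 0.01)
#' @param max_maf analysis marker set cap on pooled founder MAF
#'   (default 0.05)
#' @param control_ascertainment `"unaffected"` (rejection-sampled to be
#'   disease-free, the default) or `"random"` (population draw)
#' @param paf_exposure `"allele"` (default) uses the allele frequency as
#'   the exposure frequency in the PAF inversion; `"carrier"` uses the
#'   carrier frequency
#' @return list of class `study_design`
#' @export
study_design <- function(n_trios = 500, n_controls = 500,
                         trio_mix = c(EUR = 0.5, AFR = 0.5),
                         control_mix = c(EUR = 0.5, AFR = 0.5),
                         causal_fraction = 0, deleterious_fraction = 1,
                         eta = 0.01, causal_maf_cap = 0.01, max_maf = 0.05,
                         control_ascertainment = c("unaffected", "random"),
                         paf_exposure = c("allele", "carrier")) {
  stopifnot(n_trios >= 1, n_controls >= 0,
            abs(sum(trio_mix) - 1) < 1e-8, abs(sum(control_mix) - 1) < 1e-8,
            causal_fraction >= 0, causal_fraction <= 1,
            deleterious_fraction >= 0, deleterious_fraction <= 1,
            eta >= 0, eta < 1)
  structure(list(n_trios = n_trios, n_controls = n_controls,
                 trio_mix = trio_mix, control_mix = control_mix,
                 causal_fraction = causal_fraction,
                 deleterious_fraction = deleterious_fraction,
                 eta = eta, causal_maf_cap = causal_maf_cap,
                 max_maf = max_maf,
                 control_ascertainment = match.arg(control_ascertainment),
                 paf_exposure = match.arg(paf_exposure)),
            class = "study_design")
}

#' Build the two founder haplotype pools
#'
#' Draws ancestral frequencies from the truncated Beta spectrum, diverges
#' them into subpopulation frequencies by Balding-Nichols sampling
#' (`Beta(p (1 - F)/F, (1 - p)(1 - F)/F)`; at `fst = 0` both
#' subpopulations share the ancestral frequencies exactly), then fills
#' each pool with `pool_size` binary haplotypes whose sites are drawn
#' independently at the subpopulation frequencies.
#'
#' @param pm a [population_model()]
#' @return list with binary haplotype matrices `EUR` and `AFR`
#'   (`pool_size` by `L`), the ancestral frequencies `ancestral`, and the
#'   per-subpopulation target frequencies `freq`
#' @export
build_founder_pools <- function(pm) {
  p_anc <- numeric(0)
  while (length(p_anc) < pm$L) {          # truncated rejection draw
    cand <- stats::rbeta(2 * pm$L, pm$freq_shape[1], pm$freq_shape[2])
    p_anc <- c(p_anc, cand[cand > 0 & cand <= pm$freq_max])
  }
  p_anc <- p_anc[seq_len(pm$L)]
  subpop_freq <- function(p) {
    if (pm$fst == 0) return(p)
    stats::rbeta(length(p), p * (1 - pm$fst) / pm$fst,
                 (1 - p) * (1 - pm$fst) / pm$fst)
  }
  freq <- list(EUR = subpop_freq(p_anc), AFR = subpop_freq(p_anc))
  pool <- function(q) {
    matrix(stats::rbinom(pm$pool_size * pm$L, 1L, rep(q, each = pm$pool_size)),
           nrow = pm$pool_size)
  }
  list(EUR = pool(freq$EUR), AFR = pool(freq$AFR),
       ancestral = p_anc, freq = freq)
}

#' Effect size from a per-locus population attributable fraction
#'
#' Inverts the attributable-fraction relation
#' `PAF = f (RR - 1) / [1 + f (RR - 1)]` for the relative risk `RR` at
#' exposure frequency `f` and returns the log relative risk
#' `beta = ln(1 + eta / ((1 - eta) f))`. With `exposure = "allele"` the
#' exposure frequency is the allele frequency itself; `"carrier"` uses the
#' carrier frequency `2 q (1 - q) + q^2`. Rarer variants receive larger
#' effects for the same attributable fraction, and `beta` is strictly
#' decreasing in the frequency.
#'
#' @param eta population attributable fraction in `[0, 1)`
#' @param maf allele frequency in `[0, 1)`
#' @param exposure `"allele"` (default) or `"carrier"`
#' @return log relative risk (non-negative; negate for protective loci)
#' @export
paf_to_beta <- function(eta, maf, exposure = c("allele", "carrier")) {
  exposure <- match.arg(exposure)
  stopifnot(all(eta >= 0 & eta < 1), all(maf >= 0 & maf < 1))
  f <- if (exposure == "carrier") 2 * maf * (1 - maf) + maf^2 else maf
  n <- max(length(f), length(eta))
  f <- rep_len(f, n); eta <- rep_len(eta, n)
  zero <- f == 0 | eta == 0
  if (any(f == 0 & eta > 0)) {
    warning("maf = 0 at a causal locus: effect set to 0 (unobservable)")
  }
  out <- numeric(n)
  out[!zero] <- log(1 + eta[!zero] / ((1 - eta[!zero]) * f[!zero]))
  out
}

#' Disease probability of a genotype vector
#'
#' @param G genotype-score vector (0/1/2 per locus)
#' @param subpop `"EUR"` or `"AFR"` (an index into the model's
#'   prevalences)
#' @param dm a [disease_model()]
#' @return probability of being affected
#' @export
disease_probability <- function(G, subpop, dm) {
  eff <- if (length(dm$beta)) sum(dm$beta * G) else 0
  stats::plogis(dm$beta0[[subpop]] + eff)
}

# Vectorized rejection sampler shared by trios and controls.
# draw(m) must return a list(scores = m x L matrix rows, extra...) of m
# candidate subjects; keep(prob) decides acceptance from the disease
# probabilities. Returns row indices of `k` accepted candidates,
# accumulated across batches.
.rejection_sample <- function(k, draw, accept_prob, affected) {
  got <- list(); n_got <- 0L; tried <- 0
  while (n_got < k) {
    m <- min(max(2L * (k - n_got), 100L), 200000L)
    cand <- draw(m)
    pr <- accept_prob(cand)
    keep <- stats::rbinom(m, 1L, if (affected) pr else 1 - pr) == 1L
    tried <- tried + m
    if (any(keep)) {
      cand <- lapply(cand, function(x) x[keep, , drop = FALSE])
      got[[length(got) + 1L]] <- cand
      n_got <- n_got + sum(keep)
    }
    if (tried > 1e6 && n_got / tried < 1e-6) {
      stop("infeasible ascertainment: acceptance rate below 1e-6")
    }
  }
  parts <- lapply(names(got[[1]]), function(nm) {
    do.call(rbind, lapply(got, `[[`, nm))[seq_len(k), , drop = FALSE]
  })
  names(parts) <- names(got[[1]])
  parts
}

# Draw k affected-child trios from one subpopulation pool.
.sample_trios_pop <- function(pool, k, beta0, beta) {
  H <- nrow(pool); L <- ncol(pool)
  draw <- function(m) {
    hap <- function() pool[sample.int(H, m, replace = TRUE), , drop = FALSE]
    f1 <- hap(); f2 <- hap(); m1 <- hap(); m2 <- hap()
    tpat <- stats::rbinom(m, 1L, 0.5) == 1L   # which paternal haplotype
    tmat <- stats::rbinom(m, 1L, 0.5) == 1L
    cpat <- f1; cpat[tpat, ] <- f2[tpat, ]
    cmat <- m1; cmat[tmat, ] <- m2[tmat, ]
    list(father = f1 + f2, mother = m1 + m2, child = cpat + cmat)
  }
  accept_prob <- function(cand) {
    eff <- if (length(beta)) drop(cand$child %*% beta) else 0
    stats::plogis(beta0 + eff)
  }
  .rejection_sample(k, draw, accept_prob, affected = TRUE)
}

# Draw k controls (unaffected or random) from one subpopulation pool.
.sample_controls_pop <- function(pool, k, beta0, beta, ascertainment) {
  H <- nrow(pool)
  draw <- function(m) {
    g <- pool[sample.int(H, m, replace = TRUE), , drop = FALSE] +
      pool[sample.int(H, m, replace = TRUE), , drop = FALSE]
    list(scores = g)
  }
  if (ascertainment == "random") {
    g <- draw(k)$scores
    return(list(scores = g))
  }
  accept_prob <- function(cand) {
    eff <- if (length(beta)) drop(cand$scores %*% beta) else 0
    stats::plogis(beta0 + eff)
  }
  .rejection_sample(k, draw, accept_prob, affected = FALSE)
}

#' Sample one ascertained case-parent trio
#'
#' Draws the trio's subpopulation from the design's trio mixture, forms
#' each parent from two haplotypes of that subpopulation's pool, transmits
#' one haplotype per parent to the child (no within-region recombination),
#' and accepts the trio if the child is affected under the disease model
#' (rejection sampling).
#'
#' @param pools pools from [build_founder_pools()]
#' @param design a [study_design()]
#' @param dm a [disease_model()]
#' @return list with `father`, `mother`, `child` score vectors and
#'   `subpop`
#' @export
sample_trio <- function(pools, design, dm) {
  s <- sample(c("EUR", "AFR"), 1, prob = design$trio_mix)
  tr <- .sample_trios_pop(pools[[s]], 1L, dm$beta0[[s]], dm$beta)
  list(father = drop(tr$father), mother = drop(tr$mother),
       child = drop(tr$child), subpop = s)
}

#' Sample one unrelated control
#'
#' @inheritParams sample_trio
#' @return list with the control's `scores` vector and `subpop`
#' @export
sample_control <- function(pools, design, dm) {
  s <- sample(c("EUR", "AFR"), 1, prob = design$control_mix)
  ct <- .sample_controls_pop(pools[[s]], 1L, dm$beta0[[s]], dm$beta,
                             design$control_ascertainment)
  list(scores = drop(ct$scores), subpop = s)
}

#' Generate a complete synthetic stratified study
#'
#' Builds the founder pools, assigns the causal loci (a
#' `causal_fraction` of the loci with pooled founder MAF at or below the
#' causal cap, split into deleterious and protective per the design),
#' calibrates effect sizes from the per-locus attributable fraction,
#' samples the ascertained trios and the controls, and restricts the
#' variants to the analysis marker set (pooled founder MAF at or below
#' `max_maf`). Fully reproducible from `seed`.
#'
#' @param design a [study_design()]
#' @param pm a [population_model()]
#' @param seed integer seed
#' @return list with the [region_dataset()] `dataset` and a `truth` list
#'   (causal variant ids and retained indices, per-locus `beta`, pooled
#'   founder MAF, subpopulation labels, seed)
#' @export
generate_study <- function(design, pm = population_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- build_founder_pools(pm)
  pooled_maf <- (colMeans(pools$EUR) + colMeans(pools$AFR)) / 2

  eligible <- which(pooled_maf > 0 & pooled_maf <= design$causal_maf_cap)
  n_causal <- round(design$causal_fraction * length(eligible))
  causal <- sort(eligible[sample.int(length(eligible), n_causal)])
  beta <- numeric(pm$L)
  if (n_causal > 0) {
    eff <- paf_to_beta(design$eta, pooled_maf[causal],
                       exposure = design$paf_exposure)
    n_del <- round(design$deleterious_fraction * n_causal)
    sign_ <- rep(-1, n_causal)
    sign_[sample.int(n_causal, n_del)] <- 1
    beta[causal] <- sign_ * eff
  }
  dm <- disease_model(beta = beta, causal = causal)

  n_by <- function(mix, n) {       # multinomial split of subjects
    k <- stats::rbinom(1, n, mix[["EUR"]])
    c(EUR = k, AFR = n - k)
  }
  nt <- n_by(design$trio_mix, design$n_trios)
  father <- mother <- child <- NULL
  subpop_trio <- character(0)
  for (s in c("EUR", "AFR")) {
    if (nt[[s]] == 0) next
    tr <- .sample_trios_pop(pools[[s]], nt[[s]], dm$beta0[[s]], dm$beta)
    father <- rbind(father, tr$father)
    mother <- rbind(mother, tr$mother)
    child <- rbind(child, tr$child)
    subpop_trio <- c(subpop_trio, rep(s, nt[[s]]))
  }

  controls <- NULL; subpop_ctrl <- character(0)
  if (design$n_controls > 0) {
    nc <- n_by(design$control_mix, design$n_controls)
    for (s in c("EUR", "AFR")) {
      if (nc[[s]] == 0) next
      ct <- .sample_controls_pop(pools[[s]], nc[[s]], dm$beta0[[s]],
                                 dm$beta, design$control_ascertainment)
      controls <- rbind(controls, ct$scores)
      subpop_ctrl <- c(subpop_ctrl, rep(s, nc[[s]]))
    }
    rownames(controls) <- paste0("ctrl", seq_len(nrow(controls)))
  }

  variants <- data.frame(variant_id = paste0("v", seq_len(pm$L)),
                         chrom = "1", pos = seq_len(pm$L) * 100L,
                         minor_allele = "A", stringsAsFactors = FALSE)
  ds <- region_dataset(variants, father, mother, child, controls,
                       provenance = list(generator = "conada simulator",
                                         seed = seed, filters = character()))
  keep <- pooled_maf <= design$max_maf
  if (!any(keep)) stop("no variants pass the analysis MAF cap")
  ds <- .subset_variants(ds, keep, sprintf("analysis maf<=%g", design$max_maf))

  list(dataset = ds,
       truth = list(causal_ids = variants$variant_id[causal],
                    causal = match(variants$variant_id[causal],
                                   ds$variants$variant_id),
                    beta = beta, pooled_maf = pooled_maf,
                    trio_subpop = subpop_trio, control_subpop = subpop_ctrl,
                    seed = seed))
}

.subset_variants <- function(ds, keep, filter_tag) {
  ds$variants <- ds$variants[keep, , drop = FALSE]
  rownames(ds$variants) <- NULL
  ds$father <- ds$father[, keep, drop = FALSE]
  ds$mother <- ds$mother[, keep, drop = FALSE]
  ds$child  <- ds$child[, keep, drop = FALSE]
  if (!is.null(ds$controls)) ds$controls <- ds$controls[, keep, drop = FALSE]
  ds$provenance$filters <- c(ds$provenance$filters, filter_tag)
  ds
}

#' Write a simulated study as VCF + pedigree
#'
#' Emits a plain-text VCF v4.2 (one biallelic record per variant, GT-only)
#' and a 6-column pedigree compatible with [load_dataset()]. Genotypes are
#' written unphased with the minor allele as ALT.
#'
#' @param study result of [generate_study()]
#' @param vcf_path,ped_path output paths
#' @return invisibly, `vcf_path`
#' @export
write_study_vcf <- function(study, vcf_path, ped_path) {
  ds <- study$dataset
  n <- n_trios(ds)
  trio_ids <- rownames(ds$child)
  fids <- paste0(trio_ids, "_F"); mids <- paste0(trio_ids, "_M")
  ctrl_ids <- if (!is.null(ds$controls)) rownames(ds$controls) else character(0)
  samples <- c(fids, mids, trio_ids, ctrl_ids)
  scores <- rbind(ds$father, ds$mother, ds$child, ds$controls)

  gt_of <- function(s) c("0/0", "0/1", "1/1")[s + 1L]
  body <- vapply(seq_len(n_variants(ds)), function(l) {
    paste(c(ds$variants$chrom[l], ds$variants$pos[l],
            ds$variants$variant_id[l], "C", "T", ".", "PASS", ".", "GT",
            gt_of(scores[, l])), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=conada-simulator(synthetic)",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               body), vcf_path)

  ped <- rbind(
    data.frame(fid = trio_ids, iid = fids, pat = "0", mat = "0",
               sex = 1L, pheno = 1L),
    data.frame(fid = trio_ids, iid = mids, pat = "0", mat = "0",
               sex = 2L, pheno = 1L),
    data.frame(fid = trio_ids, iid = trio_ids, pat = fids, mat = mids,
               sex = 0L, pheno = 2L),
    if (length(ctrl_ids)) {
      data.frame(fid = ctrl_ids, iid = ctrl_ids, pat = "0", mat = "0",
                 sex = 0L, pheno = 1L)
    })
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(vcf_path)
}
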