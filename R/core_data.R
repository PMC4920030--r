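#' Assemble a region dataset from genotype score matrices
#'
#' A `region_dataset` holds the genotype scores of a chromosomal region for
#' `n` case-parent trios (father, mother, affected child) and, optionally,
#' unrelated population controls. Scores count copies of the minor allele
#' (0, 1 or 2); `NA` marks a missing genotype. All downstream machinery --
#' per-variant transmission statistics, weighting, permutation -- operates on
#' this container.
#'
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based) and `minor_allele`; one row per variant, in column order of
#'   the score matrices.
#' @param father,mother,child integer matrices, `n` trios by `L` variants,
#'   entries in `{0, 1, 2, NA}`. Row names (if any) are trio identifiers.
#' @param controls optional matrix of control scores, `n_controls` by `L`,
#'   same coding; row names are control identifiers.
#' @param provenance free-form list recording source paths and filters.
#'
#' @return An object of class `region_dataset` with elements `variants`,
#'   `father`, `mother`, `child`, `controls` and `provenance`.
#' @seealso [load_dataset()], [check_mendelian()], [filter_by_maf()]
#' @export
region_dataset <- function(variants, father, mother, child,
                           controls = NULL, provenance = list()) {
  father <- .as_score_matrix(father, "father")
  mother <- .as_score_matrix(mother, "mother")
  child  <- .as_score_matrix(child, "child")
  L <- ncol(child)
  n <- nrow(child)
  if (n < 1L) stop("a region_dataset needs at least one trio")
  if (ncol(father) != L || ncol(mother) != L || nrow(father) != n ||
      nrow(mother) != n) {
    stop("father, mother and child matrices must share dimensions")
  }
  if (!is.data.frame(variants) ||
      !all(c("variant_id", "chrom", "pos", "minor_allele") %in% names(variants))) {
    stop("variants must be a data frame with variant_id, chrom, pos, minor_allele")
  }
  if (nrow(variants) != L) stop("variants table must have one row per column of the score matrices")
  if (anyDuplicated(variants$variant_id)) stop("variant_id values must be unique")
  if (any(variants$pos < 1L)) stop("positions are 1-based and must be >= 1")
  if (!is.null(controls)) {
    controls <- .as_score_matrix(controls, "controls")
    if (ncol(controls) != L) stop("control matrix must have L columns")
  }
  if (is.null(rownames(child))) {
    ids <- paste0("trio", seq_len(n))
    rownames(father) <- rownames(mother) <- rownames(child) <- ids
  }
  structure(
    list(variants = variants, father = father, mother = mother,
         child = child, controls = controls, provenance = provenance),
    class = "region_dataset"
  )
}

.as_score_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  bad <- !is.na(x) & !(x %in% 0:2)
  if (any(bad)) stop(sprintf("%s scores must be 0, 1, 2 or NA", what))
  x
}

#' @export
print.region_dataset <- function(x, ...) {
  cat(sprintf("region_dataset: %d trios, %d variants, %s controls\n",
              nrow(x$child), ncol(x$child),
              if (is.null(x$controls)) "no" else nrow(x$controls)))
  invisible(x)
}

#' Number of trios and variants
#' @param ds a `region_dataset`
#' @return integer count
#' @export
n_trios <- function(ds) nrow(ds$child)

#' @rdname n_trios
#' @export
n_variants <- function(ds) ncol(ds$child)

# Trio-locus mask: TRUE where all three members are observed.  A trio-locus
# with any missing member contributes nothing to the statistic at that locus
# and stays missing under permutation.
.trio_complete <- function(ds) {
  !is.na(ds$father) & !is.na(ds$mother) & !is.na(ds$child)
}

#' Load trio (and control) genotypes from VCF or TSV plus a pedigree
#'
#' Reads a biallelic genotype source and a 6-column PED-style pedigree
#' (FID, IID, PAT, MAT, SEX, PHENO) and assembles a [region_dataset()].
#' A pedigree row with an affected individual (PHENO = 2) whose PAT and MAT
#' are both non-zero defines a trio; a founder row (PAT = MAT = 0) with
#' PHENO = 1 is treated as an unrelated control. Other rows (the parents
#' themselves) are looked up by identifier.
#'
#' Genotype scores count the allele that is minor among founders (trio
#' parents plus controls, pooled); when the two alleles are equally frequent
#' the VCF ALT allele is counted. Half-missing or non-diploid VCF genotypes
#' are set missing with a warning. Multi-allelic sites are rejected unless
#' `split_multiallelic = TRUE`, in which case each ALT allele becomes its own
#' biallelic record.
#'
#' @param genotype_source path to a VCF (v4.x, plain text or bgzipped) or,
#'   with `format = "tsv"`, a tab-separated table whose rows are samples
#'   (first column the sample identifier) and whose remaining columns are
#'   variants with entries 0/1/2/NA.
#' @param pedigree path to the pedigree file (whitespace-separated, no
#'   header; a leading `#` header line is tolerated).
#' @param region optional `"chrom:start-end"` string restricting the
#'   variants (1-based, inclusive).
#' @param format `"vcf"` (default) or `"tsv"`.
#' @param split_multiallelic decompose multi-allelic VCF records instead of
#'   rejecting them.
#' @param mendelian_policy `"error"` (default) aborts on any Mendelian
#'   inconsistency; `"set-missing"` silences the offending trio-locus.
#' @return a [region_dataset()]
#' @export
load_dataset <- function(genotype_source, pedigree, region = NULL,
                         format = c("vcf", "tsv"),
                         split_multiallelic = FALSE,
                         mendelian_policy = c("error", "set-missing")) {
  format <- match.arg(format)
  mendelian_policy <- match.arg(mendelian_policy)
  ped <- .read_pedigree(pedigree)

  gt <- if (format == "vcf") {
    .read_vcf_scores(genotype_source, region, split_multiallelic)
  } else {
    .read_tsv_scores(genotype_source, region)
  }

  need <- unique(c(ped$trios$child, ped$trios$father, ped$trios$mother,
                   ped$controls))
  missing_samples <- setdiff(need, rownames(gt$scores))
  if (length(missing_samples)) {
    stop("sample not found in genotype source: ",
         paste(missing_samples, collapse = ", "))
  }

  father <- gt$scores[ped$trios$father, , drop = FALSE]
  mother <- gt$scores[ped$trios$mother, , drop = FALSE]
  child  <- gt$scores[ped$trios$child,  , drop = FALSE]
  rownames(father) <- rownames(mother) <- rownames(child) <- ped$trios$child
  controls <- if (length(ped$controls)) {
    gt$scores[ped$controls, , drop = FALSE]
  } else NULL

  # orient every column to the founder minor allele
  founder <- rbind(father, mother, controls)
  freq <- colMeans(founder, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  flip <- freq > 0.5                       # ties at 0.5 keep the ALT allele
  if (any(flip)) {
    father[, flip] <- 2L - father[, flip]
    mother[, flip] <- 2L - mother[, flip]
    child[, flip]  <- 2L - child[, flip]
    if (!is.null(controls)) controls[, flip] <- 2L - controls[, flip]
    ma <- gt$variants$minor_allele
    gt$variants$minor_allele[flip] <- gt$variants$other_allele[flip]
    gt$variants$other_allele[flip] <- ma[flip]
  }
  gt$variants$other_allele <- NULL

  ds <- region_dataset(gt$variants, father, mother, child, controls,
                       provenance = list(genotype_source = genotype_source,
                                         pedigree = pedigree,
                                         region = region,
                                         filters = character()))
  bad <- check_mendelian(ds)
  if (nrow(bad)) {
    if (mendelian_policy == "error") {
      stop(sprintf("%d Mendelian inconsistencies (first: trio %s at %s); %s",
                   nrow(bad), bad$trio_id[1], bad$variant_id[1],
                   "rerun with mendelian_policy = \"set-missing\" to mask them"))
    }
    idx <- cbind(match(bad$trio_id, rownames(ds$child)),
                 match(bad$variant_id, ds$variants$variant_id))
    ds$child[idx] <- NA_integer_
    warning(sprintf("%d Mendelian-inconsistent trio-loci set missing", nrow(bad)))
  }
  ds
}

.read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  ped$pat <- as.character(ped$pat); ped$mat <- as.character(ped$mat)
  ped$iid <- as.character(ped$iid)
  is_child <- ped$pheno == 2 & ped$pat != "0" & ped$mat != "0"
  # founders who are not themselves a trio parent are unrelated controls
  parent_ids <- unique(c(ped$pat[is_child], ped$mat[is_child]))
  is_control <- ped$pheno == 1 & ped$pat == "0" & ped$mat == "0" &
    !(ped$iid %in% parent_ids)
  if (!any(is_child)) stop("pedigree defines no affected-child trios")
  list(trios = data.frame(child = ped$iid[is_child],
                          father = ped$pat[is_child],
                          mother = ped$mat[is_child],
                          stringsAsFactors = FALSE),
       controls = ped$iid[is_control])
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("region must look like chrom:start-end")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

.read_vcf_scores <- function(path, region, split_multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, names(gt_raw)))
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi) && !split_multiallelic) {
    stop("multi-allelic sites present (e.g. ", fix$ID[which(multi)[1]],
         "); rerun with split_multiallelic = TRUE or normalise the VCF")
  }

  rows <- list(); vtab <- list()
  for (k in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[k], ",", fixed = TRUE)[[1]]
    gtk <- gt_raw[k, ]
    alleles <- strsplit(gtk, "[/|]")
    for (a in seq_along(alts)) {
      sc <- vapply(alleles, function(al) {
        if (length(al) != 2L || anyNA(al) || any(al == ".")) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      if (any(lengths(alleles) != 2L & !vapply(alleles, function(al)
        length(al) == 1L && (is.na(al) || al == "."), logical(1)))) {
        warning("non-diploid genotypes at ", fix$ID[k], " treated as missing")
      }
      vid <- if (length(alts) > 1L) paste0(fix$ID[k], "_", alts[a]) else fix$ID[k]
      rows[[length(rows) + 1L]] <- sc
      vtab[[length(vtab) + 1L]] <- data.frame(
        variant_id = vid, chrom = fix$CHROM[k], pos = as.integer(fix$POS[k]),
        minor_allele = alts[a], other_allele = fix$REF[k],
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(cbind, rows)
  rownames(scores) <- colnames(gt_raw)
  variants <- do.call(rbind, vtab)
  colnames(scores) <- variants$variant_id
  .apply_region(scores, variants, region)
}

.read_tsv_scores <- function(path, region) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  scores <- as.matrix(tab)
  storage.mode(scores) <- "integer"
  variants <- data.frame(variant_id = colnames(scores),
                         chrom = "NA", pos = seq_len(ncol(scores)),
                         minor_allele = "A", other_allele = "a",
                         stringsAsFactors = FALSE)
  .apply_region(scores, variants, region)
}

.apply_region <- function(scores, variants, region) {
  if (!is.null(region)) {
    r <- .parse_region(region)
    keep <- variants$chrom == r$chrom & variants$pos >= r$start &
      variants$pos <= r$end
    if (!any(keep)) stop("no variants fall inside region ", region)
    scores <- scores[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
    rownames(variants) <- NULL
  }
  list(scores = scores, variants = variants)
}

#' List Mendelian inconsistencies
#'
#' A child score is compatible with its parents when it can be written as
#' the sum of one transmitted allele count from each parent: a homozygous
#' parent (0 or 2) transmits its allele deterministically, a heterozygous
#' parent transmits either allele. Trio-loci with any missing member are
#' skipped.
#'
#' @param ds a [region_dataset()]
#' @return data frame with columns `trio_id` and `variant_id`, one row per
#'   incompatible trio-locus (zero rows when the dataset is fully
#'   compatible).
#' @export
check_mendelian <- function(ds) {
  f <- ds$father; m <- ds$mother; c_ <- ds$child
  ok <- .trio_complete(ds)
  # transmissible allele counts: T(0)={0}, T(1)={0,1}, T(2)={1}
  lo <- (f == 2) + (m == 2)              # min transmissible sum
  hi <- 2L - (f == 0) - (m == 0)         # max transmissible sum
  bad <- ok & (c_ < lo | c_ > hi)
  idx <- which(bad, arr.ind = TRUE)
  data.frame(trio_id = rownames(ds$child)[idx[, 1]],
             variant_id = ds$variants$variant_id[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Founder minor-allele frequency per variant
#'
#' Allele frequency computed from trio parents plus controls (each parent
#' counted once per trio), the reference sample used by [filter_by_maf()].
#' @param ds a [region_dataset()]
#' @return numeric vector of length `L`
#' @export
founder_maf <- function(ds) {
  founder <- rbind(ds$father, ds$mother, ds$controls)
  freq <- colMeans(founder, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  freq
}

#' Restrict a region dataset to rare variants
#'
#' Keeps variants whose founder minor-allele frequency (parents plus
#' controls; see [founder_maf()]) does not exceed `max_maf`. Row order of
#' trios and controls is preserved and the filter is recorded in the
#' dataset's provenance.
#'
#' @param ds a [region_dataset()]
#' @param max_maf frequency cap in (0, 0.5]
#' @return the filtered [region_dataset()]
#' @export
filter_by_maf <- function(ds, max_maf) {
  stopifnot(max_maf > 0, max_maf <= 0.5)
  keep <- founder_maf(ds) <= max_maf
  if (!any(keep)) stop("no variants pass MAF filter (max_maf = ", max_maf, ")")
  ds$variants <- ds$variants[keep, , drop = FALSE]
  rownames(ds$variants) <- NULL
  ds$father <- ds$father[, keep, drop = FALSE]
  ds$mother <- ds$mother[, keep, drop = FALSE]
  ds$child  <- ds$child[, keep, drop = FALSE]
  if (!is.null(ds$controls)) ds$controls <- ds$controls[, keep, drop = FALSE]
  ds$provenance$filters <- c(ds$provenance$filters,
                             sprintf("maf<=%g", max_maf))
  ds
}

#' Write conADA results to TSV
#'
#' Writes a one-row region summary (adjusted P-value, permutations used,
#' per-threshold diagnostics) to `path`, and a per-variant companion table
#' (`<path minus extension>_variants.tsv`) with each variant's asymptotic
#' P-value, weight and Manhattan-ready columns (chrom, pos, -log10 P).
#'
#' @param result a `conada_result` from [run_conada()]
#' @param path output TSV path for the region summary
#' @return invisibly, the path of the per-variant table
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "conada_result"))
  best <- which.min(result$per_threshold$p_j)
  region <- data.frame(
    adjusted_p = result$adjusted_p,
    B_used = result$B_used,
    stopped_early = result$stopped_early,
    mode = result$mode,
    best_theta = result$per_threshold$theta[best],
    best_S = result$per_threshold$S_j[best],
    min_p = min(result$per_threshold$p_j),
    seed = result$seed
  )
  utils::write.table(region, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pv <- result$per_variant
  pv$neg_log10_p <- -log10(pv$p_l)
  vpath <- sub("\\.tsv$", "", path)
  vpath <- paste0(vpath, "_variants.tsv")
  utils::write.table(pv, vpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vpath)
}
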