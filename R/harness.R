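#' Run conADA on genotype files
#'
#' File-based front end: loads a VCF (or TSV) plus pedigree, applies the
#' analysis MAF cap, runs [run_conada()] and writes the region and
#' per-variant TSVs via [write_results()].
#'
#' @inheritParams load_dataset
#' @param mode `"PC"` or `"MAF"` (see [run_conada()])
#' @param max_maf analysis cap on founder MAF (default 0.05)
#' @param grid a [threshold_grid()]
#' @param cfg a [sequential_config()]
#' @param seed integer seed
#' @param out_prefix path prefix for the output TSVs (`<prefix>.tsv` and
#'   `<prefix>_variants.tsv`); `NULL` skips writing
#' @return the `conada_result`, invisibly when writing
#' @export
conada_run <- function(genotype_source, pedigree, region = NULL,
                       format = c("vcf", "tsv"), mode = c("PC", "MAF"),
                       max_maf = 0.05, grid = threshold_grid(),
                       cfg = sequential_config(), seed = NULL,
                       out_prefix = NULL,
                       mendelian_policy = c("error", "set-missing")) {
  mode <- match.arg(mode)
  ds <- load_dataset(genotype_source, pedigree, region = region,
                     format = match.arg(format),
                     mendelian_policy = match.arg(mendelian_policy))
  ds <- filter_by_maf(ds, max_maf)
  res <- run_conada(ds, mode = mode, grid = grid, cfg = cfg, seed = seed)
  if (!is.null(out_prefix)) {
    write_results(res, paste0(out_prefix, ".tsv"))
    return(invisible(res))
  }
  res
}

#' Type-I error / power experiment harness
#'
#' Replicates the simulation experiment: generates `reps` independent
#' studies under a [study_design()], runs conADA on each, and tabulates
#' the proportion of adjusted P-values at or below each nominal level with
#' its binomial standard error. With `causal_fraction = 0` the rejection
#' proportions estimate the type-I error; otherwise they estimate power.
#' Replicate seeds are derived deterministically from `seed` (replicate
#' `i` uses `seed + i`), so any single replicate can be rerun exactly.
#'
#' @param design a [study_design()]
#' @param pm a [population_model()]
#' @param reps number of replicate studies
#' @param alpha numeric vector of nominal significance levels
#' @param mode `"PC"` or `"MAF"`
#' @param grid a [threshold_grid()]
#' @param cfg a [sequential_config()]
#' @param seed base integer seed
#' @return list with `table` (data frame: alpha, rejections, proportion,
#'   se) and the vector of adjusted P-values `pvalues`
#' @export
conada_power <- function(design, pm = population_model(), reps = 100,
                         alpha = c(0.05, 0.01), mode = c("PC", "MAF"),
                         grid = threshold_grid(),
                         cfg = sequential_config(), seed = 1) {
  mode <- match.arg(mode)
  pvals <- vapply(seq_len(reps), function(i) {
    study <- generate_study(design, pm, seed = seed + i)
    run_conada(study$dataset, mode = mode, grid = grid, cfg = cfg,
               seed = NULL)$adjusted_p
  }, numeric(1))
  tab <- data.frame(
    alpha = alpha,
    rejections = vapply(alpha, function(a) sum(pvals <= a), numeric(1)),
    reps = reps
  )
  tab$proportion <- tab$rejections / reps
  tab$se <- sqrt(tab$proportion * (1 - tab$proportion) / reps)
  list(table = tab, pvalues = pvals)
}
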