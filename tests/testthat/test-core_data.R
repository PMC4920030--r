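test_that("region_dataset validates shapes, scores and variant metadata", {
  ds <- make_ds(c(1L, 0L), c(0L, 2L), c(1L, 1L))
  expect_s3_class(ds, "region_dataset")
  expect_equal(n_trios(ds), 1L)
  expect_equal(n_variants(ds), 2L)

  expect_error(make_ds(3L, 0L, 1L), "scores must be")
  expect_error(make_ds(c(1L, 0L), 0L, 0L), "share dimensions")
  v <- data.frame(variant_id = c("a", "a"), chrom = "1", pos = c(1L, 2L),
                  minor_allele = "A")
  expect_error(region_dataset(v, rbind(c(0L, 0L)), rbind(c(0L, 0L)),
                              rbind(c(0L, 0L))), "unique")
})

test_that("TSV dialect + pedigree loading resolves trios, controls, regions", {
  tsv <- tempfile(fileext = ".tsv"); ped <- tempfile(fileext = ".ped")
  gm <- rbind(F1 = c(1L, 0L, 2L), M1 = c(0L, 1L, 1L),
              C1 = c(1L, 1L, 2L), U1 = c(0L, 0L, 1L))
  write.table(data.frame(sample = rownames(gm), gm),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("sample", "s1", "s2", "s3"))
  writeLines(c("T1\tF1\t0\t0\t1\t1", "T1\tM1\t0\t0\t2\t1",
               "T1\tC1\tF1\tM1\t0\t2", "U1\tU1\t0\t0\t0\t1"), ped)

  ds <- load_dataset(tsv, ped, format = "tsv")
  expect_equal(n_trios(ds), 1L)
  expect_equal(n_variants(ds), 3L)
  expect_equal(nrow(ds$controls), 1L)
  # s3 founder frequency is 4/6 > 0.5, so the loader flips its coding
  expect_equal(unname(ds$child[1, ]), c(1L, 1L, 0L))

  # region filter keeps a single site (TSV positions are column indices)
  ds1 <- load_dataset(tsv, ped, region = "NA:2-2", format = "tsv")
  expect_equal(n_variants(ds1), 1L)
  expect_equal(ds1$variants$variant_id, "s2")

  # pedigree member absent from the genotype source is named in the error
  writeLines(c("T1\tC1\tFX\tM1\t0\t2", "T1\tM1\t0\t0\t2\t1"), ped)
  expect_error(load_dataset(tsv, ped, format = "tsv"),
               "sample not found.*FX")
})

write_test_vcf <- function(path, alt2 = "T") {
  # 3 samples (father, mother, child) + 1 control; site v2 has ALT as the
  # major allele so the loader must flip the orientation
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "F1", "M1", "C1", "U1", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/1", "0/0", sep = "\t"),
    paste("1", "200", "v2", "A", alt2, ".", "PASS", ".", "GT",
          "1/1", "1/1", "1/1", "0/1", sep = "\t")), path)
}

test_that("VCF loading orients scores to the founder minor allele", {
  vcf <- tempfile(fileext = ".vcf"); ped <- tempfile(fileext = ".ped")
  write_test_vcf(vcf)
  writeLines(c("T1\tF1\t0\t0\t1\t1", "T1\tM1\t0\t0\t2\t1",
               "T1\tC1\tF1\tM1\t0\t2", "U1\tU1\t0\t0\t0\t1"), ped)
  ds <- load_dataset(vcf, ped)
  expect_equal(n_variants(ds), 2L)
  # v1: ALT frequency 1/6 among founders -> ALT stays the counted allele
  expect_equal(unname(ds$child[1, 1]), 1L)
  expect_equal(ds$variants$minor_allele[1], "G")
  # v2: ALT frequency 5/6 among founders -> flipped to count REF
  expect_equal(unname(ds$child[1, 2]), 0L)
  expect_equal(ds$variants$minor_allele[2], "A")
  expect_equal(unname(ds$controls[1, 2]), 1L)
})

test_that("multi-allelic records are rejected by default and split on request", {
  vcf <- tempfile(fileext = ".vcf"); ped <- tempfile(fileext = ".ped")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "F1", "M1", "C1", sep = "\t"),
    paste("1", "100", "v1", "A", "G,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/2", sep = "\t")), vcf)
  writeLines(c("T1\tF1\t0\t0\t1\t1", "T1\tM1\t0\t0\t2\t1",
               "T1\tC1\tF1\tM1\t0\t2"), ped)
  expect_error(load_dataset(vcf, ped), "multi-allelic")
  ds <- load_dataset(vcf, ped, split_multiallelic = TRUE)
  expect_equal(n_variants(ds), 2L)
  expect_equal(unname(ds$child[1, ]), c(1L, 1L))   # one G, one T
})

test_that("check_mendelian flags exactly the impossible transmissions", {
  # f=0, m=0 cannot produce a het child
  ds <- make_ds(c(0L, 1L, 2L), c(0L, 1L, 0L), c(1L, 1L, 1L))
  bad <- check_mendelian(ds)
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$variant_id, "v1")

  # f=1, m=1 is compatible with any child score
  for (cc in 0:2) {
    expect_equal(nrow(check_mendelian(make_ds(1L, 1L, cc))), 0L)
  }
  # f=2, m=0 forces a het child
  expect_equal(nrow(check_mendelian(make_ds(2L, 0L, 1L))), 0L)
  expect_equal(nrow(check_mendelian(make_ds(2L, 0L, 2L))), 1L)
  # missing members are skipped
  expect_equal(nrow(check_mendelian(make_ds(NA_integer_, 0L, 2L))), 0L)
})

test_that("filter_by_maf keeps rare variants and composes by the tighter cap", {
  set.seed(11)
  ds <- random_trio_dataset(40, 6, maf = 0.2, controls = 30)
  freq <- founder_maf(ds)
  kept <- filter_by_maf(ds, 0.25)
  expect_equal(n_variants(kept), sum(freq <= 0.25))
  expect_true(all(founder_maf(kept) <= 0.25))
  expect_match(kept$provenance$filters, "maf<=0.25")

  # composition: filtering at a then b equals filtering at min(a, b)
  ab <- filter_by_maf(filter_by_maf(ds, 0.4), 0.25)
  expect_equal(ab$variants$variant_id, kept$variants$variant_id)
  expect_equal(ab$child, kept$child)

  # max_maf = 0.5 keeps everything; an impossible cap errors
  expect_equal(n_variants(filter_by_maf(ds, 0.5)), 6L)
  expect_error(filter_by_maf(ds, 1e-6), "no variants pass")

  # a monomorphic site (frequency 0) passes any cap
  mono <- make_ds(c(0L, 1L), c(0L, 1L), c(0L, 1L))
  expect_true("v1" %in% filter_by_maf(mono, 0.05)$variants$variant_id)
})

test_that("results round-trip through the TSV writer", {
  set.seed(21)
  ds <- random_trio_dataset(30, 5, maf = 0.1, controls = 30)
  res <- run_conada(ds, mode = "PC", cfg = sequential_config(10, 200),
                    seed = 5)
  path <- tempfile(fileext = ".tsv")
  vpath <- write_results(res, path)

  region <- read.delim(path)
  expect_equal(region$adjusted_p, res$adjusted_p, tolerance = 1e-6)
  expect_equal(region$B_used, res$B_used)

  pv <- read.delim(vpath)
  expect_equal(nrow(pv), n_variants(ds))
  expect_equal(pv$p_l, res$per_variant$p_l, tolerance = 1e-6)
  expect_equal(pv$neg_log10_p, -log10(res$per_variant$p_l),
               tolerance = 1e-6)
  expect_true(all(c("chrom", "pos") %in% names(pv)))
})

test_that("a simulated study survives a VCF round trip unchanged", {
  design <- study_design(n_trios = 20, n_controls = 15)
  study <- generate_study(design, population_model(L = 12, pool_size = 500),
                          seed = 33)
  vcf <- tempfile(fileext = ".vcf"); ped <- tempfile(fileext = ".ped")
  write_study_vcf(study, vcf, ped)
  ds2 <- load_dataset(vcf, ped)
  ds1 <- study$dataset
  expect_equal(unname(ds2$child), unname(ds1$child))
  expect_equal(unname(ds2$father), unname(ds1$father))
  expect_equal(unname(ds2$mother), unname(ds1$mother))
  expect_equal(unname(ds2$controls), unname(ds1$controls))
  expect_equal(ds2$variants$variant_id, ds1$variants$variant_id)
  expect_equal(nrow(check_mendelian(ds2)), 0L)
})
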