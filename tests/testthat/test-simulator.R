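test_that("PAF inversion gives the closed-form log relative risk", {
  expect_equal(paf_to_beta(0, 0.01), 0)
  expect_equal(paf_to_beta(0.01, 0.005),
               log(1 + 0.01 / (0.99 * 0.005)), tolerance = 1e-12)
  expect_equal(paf_to_beta(0.01, 0.005), 1.1053237, tolerance = 1e-6)
  # strictly decreasing in MAF at fixed eta
  b <- paf_to_beta(0.02, c(0.001, 0.005, 0.01, 0.05))
  expect_true(all(diff(b) < 0))
  # carrier-frequency exposure is commoner, so the effect is smaller
  expect_lt(paf_to_beta(0.01, 0.01, exposure = "carrier"),
            paf_to_beta(0.01, 0.01))
  expect_warning(paf_to_beta(0.01, 0), "unobservable")
})

test_that("disease probability is the logistic penetrance", {
  dm <- disease_model(beta = c(0.5, -0.3), causal = 1:2)
  expect_equal(dm$beta0[["EUR"]], qlogis(0.05), tolerance = 1e-12)
  expect_equal(qlogis(0.05), -2.944439, tolerance = 1e-6)
  # intercept-only: baseline prevalence
  expect_equal(disease_probability(c(0, 0), "EUR", dm), 0.05)
  expect_equal(disease_probability(c(0, 0), "AFR", dm), 0.01)
  # protective allele lowers the probability
  expect_lt(disease_probability(c(0, 1), "AFR", dm),
            disease_probability(c(0, 0), "AFR", dm))
  expect_gt(disease_probability(c(1, 0), "AFR", dm),
            disease_probability(c(0, 0), "AFR", dm))
})

test_that("founder pools hit their target frequencies", {
  set.seed(501)
  pm0 <- population_model(L = 20, fst = 0, pool_size = 5000)
  pools <- build_founder_pools(pm0)
  # fst = 0: both subpopulations share the ancestral expectations
  expect_equal(pools$freq$EUR, pools$ancestral)
  expect_equal(pools$freq$AFR, pools$ancestral)
  expect_true(all(pools$ancestral > 0 & pools$ancestral <= 0.05))
  # pool empirical frequency within 3 binomial SE of target
  emp <- colMeans(pools$EUR)
  se <- sqrt(pools$freq$EUR * (1 - pools$freq$EUR) / 5000)
  expect_true(all(abs(emp - pools$freq$EUR) <= 3 * se + 1e-9))

  pm <- population_model(L = 20, fst = 0.2, pool_size = 1000)
  pools2 <- build_founder_pools(pm)
  expect_false(identical(pools2$freq$EUR, pools2$freq$AFR))
})

test_that("simulated studies are Mendelian-consistent and reproducible", {
  design <- study_design(n_trios = 30, n_controls = 20)
  pm <- population_model(L = 15, pool_size = 1000)
  s1 <- generate_study(design, pm, seed = 7)
  s2 <- generate_study(design, pm, seed = 7)
  expect_identical(s1$dataset$child, s2$dataset$child)
  expect_identical(s1$dataset$controls, s2$dataset$controls)
  expect_equal(nrow(check_mendelian(s1$dataset)), 0L)
  # null design: no causal loci in the truth
  expect_length(s1$truth$causal_ids, 0)
  # analysis marker cap respected (on pooled founder-pool frequencies)
  idx1 <- as.integer(sub("v", "", s1$dataset$variants$variant_id))
  expect_true(all(s1$truth$pooled_maf[idx1] <= design$max_maf))

  s3 <- generate_study(design, pm, seed = 8)
  expect_false(identical(s1$dataset$child, s3$dataset$child))

  # causal designs record the causal set and effect signs
  dsgn <- study_design(n_trios = 20, n_controls = 0, causal_fraction = 1,
                       deleterious_fraction = 0.5, eta = 0.02)
  s4 <- generate_study(dsgn, pm, seed = 9)
  expect_gt(length(s4$truth$causal_ids), 0)
  expect_true(all(s4$truth$beta[s4$truth$beta != 0] != 0))
  expect_true(is.null(s4$dataset$controls))
})

test_that("null ascertainment leaves transmissions balanced; deleterious loci are over-transmitted", {
  set.seed(502)
  # eta = 0: affected-child ascertainment carries no genotype information,
  # so the aggregate standardized transmission deviation is ~ N(0, 1)
  null_study <- generate_study(
    study_design(n_trios = 300, n_controls = 0),
    population_model(L = 25, pool_size = 2000), seed = 11)
  ts <- conada:::transmission_summary(null_study$dataset)
  z_null <- sum(ts$d) / sqrt(sum(ts$v))
  expect_lt(abs(z_null), 4)

  # strong deleterious effects: ascertainment induces over-transmission
  # of the minor allele at causal loci
  pow_study <- generate_study(
    study_design(n_trios = 500, n_controls = 0, causal_fraction = 1,
                 deleterious_fraction = 1, eta = 0.05),
    population_model(L = 25, pool_size = 2000), seed = 12)
  tsp <- conada:::transmission_summary(pow_study$dataset)
  causal <- pow_study$truth$causal
  causal <- causal[!is.na(causal)]
  z_causal <- sum(tsp$d[causal]) / sqrt(sum(tsp$v[causal]))
  expect_gt(z_causal, 2.33)
})

test_that("controls reflect their subpopulation mixture and the prevalence model", {
  set.seed(503)
  pm <- population_model(L = 10, pool_size = 2000)
  # all-AFR control mixture
  s <- generate_study(study_design(n_trios = 5, n_controls = 50,
                                   control_mix = c(EUR = 0, AFR = 1)),
                      pm, seed = 21)
  expect_true(all(s$truth$control_subpop == "AFR"))

  # under the null, control allele frequencies track the source pool:
  # rebuilding the pools from the same seed reproduces the generator's
  # pools exactly (pool construction is the first draw of the stream)
  pm2 <- population_model(L = 10, pool_size = 5000)
  s2 <- generate_study(study_design(n_trios = 5, n_controls = 2000,
                                    control_mix = c(EUR = 0, AFR = 1)),
                       pm2, seed = 22)
  set.seed(22)
  pools22 <- build_founder_pools(pm2)
  idx <- as.integer(sub("v", "", s2$dataset$variants$variant_id))
  ctrl_freq <- colMeans(s2$dataset$controls) / 2
  pool_freq <- colMeans(pools22$AFR)[idx]
  se <- sqrt(pmax(pool_freq * (1 - pool_freq), 2.5e-5) / (2 * 2000))
  expect_true(all(abs(ctrl_freq - pool_freq) <= 3.5 * se))

  # realized prevalence of unascertained individuals matches K
  dm <- disease_model()
  pools <- build_founder_pools(pm)
  g <- pools$AFR[sample.int(2000, 20000, replace = TRUE), ] +
    pools$AFR[sample.int(2000, 20000, replace = TRUE), ]
  pr <- plogis(qlogis(0.01) + drop(g %*% numeric(10)))
  affected <- rbinom(20000, 1, pr)
  expect_lt(abs(mean(affected) - 0.01), 3 * sqrt(0.01 * 0.99 / 20000))
})

test_that("single-subject samplers agree with the design contracts", {
  set.seed(504)
  pm <- population_model(L = 8, pool_size = 500)
  pools <- build_founder_pools(pm)
  dm <- disease_model(beta = numeric(8))
  design <- study_design(n_trios = 5, n_controls = 5)
  tr <- sample_trio(pools, design, dm)
  expect_length(tr$child, 8)
  expect_true(tr$subpop %in% c("EUR", "AFR"))
  ds <- make_ds(tr$father, tr$mother, tr$child)
  expect_equal(nrow(check_mendelian(ds)), 0L)
  ct <- sample_control(pools, design, dm)
  expect_true(all(ct$scores %in% 0:2))
})
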