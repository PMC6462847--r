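# The synthetic-data generator: LD structure, Hardy-Weinberg behaviour,
# liability-threshold disease, ascertained trios, determinism.

test_that("haplotype pools hit target MAFs, block structure and determinism", {
  pool <- make_haplotype_pool(12, maf_low = 0.1, maf_high = 0.5,
                              block_sizes = c(4, 4, 4),
                              within_block_rho = c(0.9, 0, 0.5),
                              pool_size = 5000, seed = 42)
  expect_true(all(diff(pool$snp_info$pos) > 0))
  emp <- colMeans(pool$haplotypes)
  expect_true(all(abs(emp - pool$snp_info$maf) < 0.05))

  # cross-block independence
  panel <- draw_genotypes(pool, 5000, seed = 7)
  r <- cor(panel$dosage)
  cross <- abs(r[pool$snp_info$block == 1, pool$snp_info$block == 2])
  expect_lt(max(cross), 0.05)

  pool2 <- make_haplotype_pool(12, maf_low = 0.1, maf_high = 0.5,
                               block_sizes = c(4, 4, 4),
                               within_block_rho = c(0.9, 0, 0.5),
                               pool_size = 5000, seed = 42)
  expect_identical(pool$haplotypes, pool2$haplotypes)
  expect_identical(pool$snp_info, pool2$snp_info)
})

test_that("rho = 0 gives near-zero LD and rho = 0.95 gives genotype r2 > 0.6", {
  indep <- make_haplotype_pool(6, 0.2, 0.4, block_sizes = rep(1, 6),
                               within_block_rho = 0, pool_size = 10000,
                               seed = 3)
  r <- cor(draw_genotypes(indep, 10000, seed = 4)$dosage)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  tight <- make_haplotype_pool(2, 0.3, 0.3, block_sizes = 2,
                               within_block_rho = 0.95, pool_size = 10000,
                               seed = 5, mafs = c(0.3, 0.3))
  g <- draw_genotypes(tight, 10000, seed = 6)$dosage
  expect_gt(cor(g[, 1], g[, 2])^2, 0.6)
})

test_that("latent_rho_for_allele_r inverts the dichotomized-Gaussian LD map", {
  lat <- latent_rho_for_allele_r(0.7, 0.3, 0.35)
  pool <- make_haplotype_pool(2, 0.3, 0.35, block_sizes = 2,
                              within_block_rho = lat, pool_size = 50000,
                              seed = 11, mafs = c(0.3, 0.35))
  r_hap <- cor(pool$haplotypes[, 1], pool$haplotypes[, 2])
  expect_equal(r_hap, 0.7, tolerance = 0.02)
})

test_that("pool construction rejects invalid parameters", {
  expect_error(make_haplotype_pool(4, maf_low = 0, block_sizes = 4),
               "MAF range")
  expect_error(make_haplotype_pool(4, block_sizes = c(2, 3)),
               "block_sizes")
  expect_error(make_haplotype_pool(4, block_sizes = 4, pool_size = 10),
               "pool_size")
  expect_error(make_haplotype_pool(4, block_sizes = 4,
                                   within_block_rho = 1), "rho")
})

test_that("genotype draws follow Hardy-Weinberg and basic shapes", {
  pool <- make_haplotype_pool(3, 0.5, 0.5, block_sizes = rep(1, 3),
                              pool_size = 8000, seed = 9,
                              mafs = rep(0.5, 3))
  g <- draw_genotypes(pool, 10000, seed = 10)$dosage
  expect_true(all(g %in% 0:2))
  expect_equal(mean(g[, 1] == 1), 0.5, tolerance = 0.02)

  one <- draw_genotypes(pool, 1, seed = 2)
  expect_identical(dim(one$dosage), c(1L, 3L))
})

test_that("methylation is in [0,1], tracks the mQTL effect, null is flat", {
  pool <- make_haplotype_pool(4, 0.25, 0.35, block_sizes = rep(1, 4),
                              pool_size = 3000, seed = 15)
  panel <- draw_genotypes(pool, 2000, seed = 16)
  covs <- make_covariates(2000, seed = 17)
  sim <- simulate_methylation(panel, causal_snp_index = 2,
                              mqtl_effect = 0.5, covariates = covs,
                              covariate_effect_sizes = 0.1, noise_sd = 1,
                              n_cpgs = 3, seed = 18)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_true(all(rowSums(covs[, grep("^cell_", names(covs))]) - 1 < 1e-9))
  # latent-scale slope recovers the simulated effect
  slope <- coef(lm(sim$latent[, 1] ~ panel$dosage[, 2]))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.1)
  # non-causal CpG: slope consistent with zero
  fit0 <- summary(lm(sim$latent[, 2] ~ panel$dosage[, 2]))
  expect_lt(abs(fit0$coefficients[2, "t value"]), 4)
})

test_that("scenario configs enforce model/parameter consistency", {
  expect_error(scenario_config("mediation", direct_snp_to_liability = 0.5),
               "must be zero")
  expect_error(scenario_config("null", prevalence = 1.2), "prevalence")
  cfg <- scenario_config("mediation")
  expect_identical(cfg$direct_snp_to_liability, 0)
  expect_identical(cfg$liability_to_methylation, 0)
  expect_gt(cfg$mqtl_effect, 0)
  cfg_null <- scenario_config("null")
  expect_identical(cfg_null$disease_snp_liability, 0)
})

test_that("liability threshold yields the target prevalence", {
  # all effects zero: closed-form binomial check at n = 10000
  cfg <- scenario_config("null", n_individuals = 10000, n_trios = 0,
                         mqtl_effect = 0, prevalence = 0.1, seed = 31)
  dat <- generate_scenario(cfg)
  expect_lt(abs(mean(dat$bundle$phenotype) - 0.1), 0.01)

  # non-null predictor: threshold scaling keeps realized prevalence on
  # target (small residual error from the discreteness of the polygenic
  # score is tolerated)
  cfg2 <- scenario_config("mediation", n_individuals = 10000, n_trios = 0,
                          prevalence = 0.1, seed = 32)
  dat2 <- generate_scenario(cfg2)
  expect_lt(abs(mean(dat2$bundle$phenotype) - 0.1), 0.015)
})

test_that("disease is independent of methylation when no path links them", {
  cfg <- scenario_config("null", n_individuals = 4000, n_trios = 0,
                         seed = 33)
  dat <- generate_scenario(cfg)
  m <- scale(dat$bundle$methylation_latent[, 1])
  fit <- summary(glm(dat$bundle$phenotype ~ m, family = binomial()))
  expect_lt(abs(fit$coefficients["m", "z value"]), 4)
})

test_that("trios are Mendelian-consistent, ascertained, and duos maskable", {
  cfg <- scenario_config("mediation", n_individuals = 100, n_trios = 150,
                         seed = 41)
  dat <- generate_scenario(cfg)
  tr <- dat$trios
  expect_true(all(tr$child_affected))
  gf <- tr$father; gm <- tr$mother; gc <- tr$child
  lo <- (gf == 2) + (gm == 2)
  hi <- 2 - ((gf == 0) + (gm == 0))
  expect_true(all(gc >= lo & gc <= hi))

  duo <- simulate_trios(dat$pool, cfg, n_trios = 20, causal_snp_index = 11,
                        disease_snp_index = 27:32, n_duos = 5, seed = 42)
  expect_true(all(is.na(duo$father[1:5, ])))
  expect_true(all(!is.na(duo$father[6:20, ])))
})

test_that("ascertainment cap raises a clear error", {
  pool <- make_haplotype_pool(4, 0.25, 0.35, block_sizes = rep(1, 4),
                              pool_size = 200, seed = 50)
  cfg <- scenario_config("null", prevalence = 0.001, seed = 51,
                         mqtl_effect = 0)
  expect_error(
    simulate_trios(pool, cfg, n_trios = 50, causal_snp_index = 1,
                   max_families = 2000, seed = 52),
    "ascertainment cap")
})

test_that("generate_scenario is a pure function of its config", {
  cfg <- scenario_config("linkage", n_individuals = 300, n_trios = 10,
                         seed = 61)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$bundle$genotypes$dosage, b$bundle$genotypes$dosage)
  expect_identical(a$bundle$methylation, b$bundle$methylation)
  expect_identical(a$bundle$phenotype, b$bundle$phenotype)
  expect_identical(a$trios$child, b$trios$child)

  # truth-table flags follow the model
  expect_identical(sum(a$truth_table$role == "mqtl"), 1L)
  expect_true(a$truth_table$causal_for_disease[a$truth_table$role ==
                                                 "disease_linked"])
  null_dat <- generate_scenario(
    scenario_config("null", n_individuals = 100, n_trios = 0,
                    mqtl_effect = 0, seed = 62))
  expect_false(any(null_dat$truth_table$causal_for_disease))
  expect_false(any(null_dat$truth_table$causal_for_methylation))
})

test_that("linkage coupling hits the requested genotype r2", {
  cfg <- scenario_config("linkage", n_individuals = 5000, n_trios = 0,
                         linkage_r2 = 0.5, seed = 71)
  dat <- generate_scenario(cfg)
  g <- dat$bundle$genotypes$dosage
  r2 <- cor(g[, dat$indices$causal_snp], g[, dat$indices$linked_snp])^2
  expect_equal(r2, 0.5, tolerance = 0.06)
})
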