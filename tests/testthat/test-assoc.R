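# TDT, case-control association, meta-analysis, LD and clumping.

test_that("tdt_counts does single-family transmission bookkeeping", {
  # father Aa x mother aa, child Aa: one transmission of A
  tr <- manual_trios(father = 1, mother = 0, child = 1)
  cnt <- tdt_counts(tr, "snp_0001")
  expect_identical(cnt$b, 1L)
  expect_identical(cnt$c, 0L)

  # both parents heterozygous, child heterozygous: one of each
  tr2 <- manual_trios(1, 1, 1)
  cnt2 <- tdt_counts(tr2, "snp_0001")
  expect_identical(cnt2$b, 1L)
  expect_identical(cnt2$c, 1L)

  # all parents homozygous: flagged, no counts
  tr3 <- manual_trios(c(0, 2), c(0, 2), c(0, 2))
  cnt3 <- tdt_counts(tr3, "snp_0001")
  expect_true(cnt3$flagged)

  # duo with het observed parent counts only unambiguous children
  tr4 <- manual_trios(c(NA, NA), c(1, 1), c(2, 1))
  cnt4 <- tdt_counts(tr4, "snp_0001")
  expect_identical(cnt4$b, 1L)   # child homozygous: determined
  expect_identical(cnt4$c, 0L)   # child het: ambiguous, skipped
})

test_that("tdt_test matches the McNemar closed form and Haldane rule", {
  sym <- tdt_test(40, 40)
  expect_identical(sym$chisq, 0)
  expect_identical(sym$beta, 0)

  tt <- tdt_test(50, 30)
  expect_equal(tt$chisq, 5.0)
  expect_equal(tt$p, pchisq(5, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(tt$p, 4), 0.0253)

  hald <- tdt_test(10, 0)
  expect_equal(hald$beta, log(10.5 / 0.5))
  expect_equal(hald$se, sqrt(1 / 10.5 + 1 / 0.5))
  expect_error(tdt_test(0, 0), "b \\+ c")
})

test_that("null trios transmit each allele half the time", {
  cfg <- scenario_config("null", n_individuals = 10, n_trios = 2000,
                         mqtl_effect = 0, prevalence = 0.2, seed = 81)
  dat <- generate_scenario(cfg)
  cnt <- tdt_counts(dat$trios, "snp_0001")
  ratio <- cnt$b / (cnt$b + cnt$c)
  expect_lt(abs(ratio - 0.5), 0.02)
  scan <- tdt_scan(dat$trios)
  expect_true(all(scan$se > 0))
  expect_true(all(scan$p > 0 & scan$p <= 1))
})

test_that("case-control association flags degenerate SNPs and finds effects", {
  dosage <- cbind(snp_0001 = rep(1L, 400),                     # monomorphic
                  snp_0002 = rep(c(0L, 1L, 2L), length.out = 400))
  panel <- manual_panel(dosage)
  y <- c(rep(1L, 150), rep(0L, 250))
  res <- case_control_assoc(panel, y)
  expect_identical(attr(res, "dropped")$snp_id, "snp_0001")
  expect_identical(attr(res, "dropped")$reason, "monomorphic")
  expect_identical(res$snp_id, "snp_0002")

  # strong effect: OR = 2, maf 0.3, n = 2000 reaches genome-wide significance
  pool <- make_haplotype_pool(1, 0.3, 0.3, block_sizes = 1,
                              pool_size = 3000, seed = 91, mafs = 0.3)
  panel2 <- draw_genotypes(pool, 2000, seed = 92)
  g <- panel2$dosage[, 1]
  set.seed(93)
  y2 <- rbinom(2000, 1, plogis(-1.5 + log(2) * g))
  res2 <- case_control_assoc(panel2, y2)
  expect_lt(res2$p, 1e-8)
  expect_equal(res2$beta, log(2), tolerance = 0.25)

  expect_error(case_control_assoc(panel, rep(1L, 400)), "case")
})

test_that("fixed-effect meta-analysis combines, harmonizes and drops", {
  # identical studies: same beta, variance halved
  s <- ss_row("rs1", beta = 1.0, se = 1.0)
  meta <- fixed_effect_meta(list(a = s, b = s))
  expect_equal(meta$beta, 1.0)
  expect_equal(meta$se, 1 / sqrt(2))

  # hand-computed weighted mean
  s1 <- ss_row("rs2", beta = 0.4, se = 0.1)
  s2 <- ss_row("rs2", beta = 0.0, se = 0.2)
  m2 <- fixed_effect_meta(list(s1, s2))
  expect_equal(m2$beta, 0.32, tolerance = 1e-12)

  # swapped alleles with negated beta harmonize to the same answer
  s2_swapped <- ss_row("rs2", beta = 0.0, se = 0.2, ea = "G", oa = "A",
                       eaf = 0.7)
  s2_swapped$beta <- -s2_swapped$beta
  m3 <- fixed_effect_meta(list(s1, s2_swapped))
  expect_equal(m3$beta, m2$beta)
  expect_equal(m3$se, m2$se)

  # irreconcilable alleles are dropped with a reason
  s2_bad <- ss_row("rs2", beta = 0.1, se = 0.2, ea = "C", oa = "A")
  m4 <- fixed_effect_meta(list(s1, s2_bad))
  expect_true(is.null(m4) || !"rs2" %in% m4$snp_id)
  expect_identical(attr(m4, "dropped")$reason, "drop_mismatch")
})

test_that("LD matrices are unit-diagonal correlations with clear errors", {
  set.seed(101)
  g1 <- rbinom(300, 2, 0.3)
  panel <- manual_panel(cbind(snp_0001 = g1, snp_0002 = g1,
                              snp_0003 = rbinom(300, 2, 0.3)))
  r <- compute_ld(panel)
  expect_equal(diag(r), setNames(rep(1, 3), colnames(panel$dosage)))
  expect_equal(r["snp_0001", "snp_0002"], 1)
  expect_true(max(abs(r)) <= 1)

  mono <- manual_panel(cbind(snp_0001 = rep(1L, 50),
                             snp_0002 = rbinom(50, 2, 0.4)))
  expect_error(compute_ld(mono), "snp_0001")
})

test_that("clumping keeps the best SNP per LD cluster", {
  set.seed(111)
  g <- rbinom(500, 2, 0.3)
  g2 <- ifelse(runif(500) < 0.95, g, rbinom(500, 2, 0.3))  # high LD partner
  panel <- manual_panel(cbind(snp_0001 = g, snp_0002 = g2),
                        pos = c(100000, 110000))
  stats <- rbind(ss_row("snp_0001", 0.5, 0.09, pos = 100000),
                 ss_row("snp_0002", 0.3, 0.08, pos = 110000))
  stats$p <- c(1e-8, 1e-4)
  kept <- clump(stats, panel, r2_threshold = 0.001, window_kb = 250)
  expect_identical(kept, "snp_0001")

  # mutually independent SNPs are all retained
  set.seed(112)
  indep <- manual_panel(vapply(1:4, function(i) rbinom(2000, 2, 0.3),
                               integer(2000)),
                        pos = seq(1e5, by = 5e5, length.out = 4))
  stats4 <- do.call(rbind, lapply(1:4, function(i)
    ss_row(sprintf("snp_%04d", i), 0.1 * i, 0.1, pos = 1e5 + (i - 1) * 5e5)))
  kept4 <- clump(stats4, indep, r2_threshold = 0.2, window_kb = 250)
  expect_setequal(kept4, stats4$snp_id)
})

test_that("clumping matches an exhaustive reference on random instances", {
  for (s in 1:5) {
    pool <- make_haplotype_pool(20, 0.2, 0.4,
                                block_sizes = c(5, 5, 5, 5),
                                within_block_rho = c(0.9, 0.5, 0.97, 0),
                                pool_size = 1000, seed = 120 + s)
    panel <- draw_genotypes(pool, 800, seed = 130 + s)
    set.seed(140 + s)
    stats <- do.call(rbind, lapply(seq_len(20), function(i) {
      z <- rnorm(1, sd = 3)
      ss_row(pool$snp_info$snp_id[i], z * 0.1, 0.1,
             pos = pool$snp_info$pos[i])
    }))
    stats$p <- 2 * pnorm(-abs(stats$beta / stats$se))
    mine <- clump(stats, panel, r2_threshold = 0.1, window_kb = 10)
    ref <- clump_reference(stats, panel, r2_threshold = 0.1, window_kb = 10)
    expect_identical(sort(mine), sort(ref))

    # invariance to input row order
    shuffled <- stats[sample.int(nrow(stats)), ]
    expect_setequal(clump(shuffled, panel, 0.1, 10), mine)
  }
})

test_that("clump warns about SNPs missing from the LD panel", {
  set.seed(151)
  panel <- manual_panel(cbind(snp_0001 = rbinom(200, 2, 0.3)))
  stats <- rbind(ss_row("snp_0001", 0.5, 0.1, pos = 1e5),
                 ss_row("snp_9999", 0.4, 0.1, pos = 2e5))
  expect_warning(kept <- clump(stats, panel), "snp_9999")
  expect_identical(kept, "snp_0001")
})
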