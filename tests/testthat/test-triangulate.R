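# Decision-table classification, replication concordance, follow-up
# statistics, report round-trip.

fake_mr <- function(p, beta = 0.5, se = 0.1, direction = "forward") {
  data.frame(exposure = "cg", outcome = "d", method = "wald",
             n_instruments = 1L, beta = beta, se = se, p = p,
             direction = direction)
}
fake_coloc <- function(p, stat = 10) {
  structure(list(statistic = stat, p_permutation = p,
                 n_permutations = 1000L, n_snps_shared_support = 3L,
                 n_snps_distinct_support = 10L, sentinel = FALSE,
                 reason = NA_character_), class = "coloc_result")
}

test_that("the decision table assigns the four labels in gate order", {
  th <- triangulation_thresholds(forward = 7.8e-6)

  call <- classify_locus(fake_mr(1e-8), fake_mr(0.6), fake_coloc(0.001), th)
  expect_identical(call$label, "putative_mediation_or_pleiotropy")

  expect_identical(
    classify_locus(fake_mr(1e-8), fake_mr(0.6), fake_coloc(1, -16.7),
                   th)$label,
    "linkage")

  # forward gate dominates everything else
  expect_identical(
    classify_locus(fake_mr(0.5), fake_mr(1e-10), fake_coloc(0.001),
                   th)$label,
    "no_signal")

  expect_identical(
    classify_locus(fake_mr(1e-8), fake_mr(0.001), fake_coloc(0.001),
                   th)$label,
    "reverse_causation")

  sent <- methtri:::coloc_sentinel("window too sparse")
  expect_identical(
    classify_locus(fake_mr(1e-8), fake_mr(0.6), sent, th)$label,
    "indeterminate")

  # the mediation-call invariant: forward and coloc significant, reverse not
  med <- classify_locus(fake_mr(1e-8), fake_mr(0.2), fake_coloc(0.01), th)
  expect_true(med$forward$p < th$forward &&
                med$coloc$p_permutation < th$coloc &&
                med$reverse$p >= th$reverse)
})

test_that("default thresholds use the Bonferroni forward gate", {
  th <- triangulation_thresholds(n_cpgs = 6425)
  expect_equal(signif(th$forward, 2), 7.8e-6)
  expect_identical(th$reverse, 0.05)
})

test_that("replication concordance follows the sign-and-p rule", {
  disc <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                     snp_id = c("rs1", "rs2", "rs3"),
                     beta = c(0.5, -0.4, 0.3), p = c(1e-9, 1e-8, 1e-8))
  repl <- data.frame(cpg_id = c("cg1", "cg2"),
                     snp_id = c("rs1", "rs2"),
                     beta = c(0.45, 0.4), p = c(0.01, 1e-9))
  out <- replication_check(disc, repl)
  expect_identical(out$concordant, c(TRUE, FALSE))  # cg2 flips sign
  expect_identical(attr(out, "dropped")$cpg_id, "cg3")
  expect_identical(unname(attr(out, "summary")["n_concordant"]), 1L)

  same <- replication_check(disc[1, ], disc[1, ])
  expect_true(same$concordant)
})

test_that("two cohorts drawn from one truth replicate concordantly", {
  hits <- 0; tested <- 0
  for (s in 1:10) {
    cfgA <- scenario_config("mediation", n_individuals = 800, n_trios = 0,
                            seed = 7000 + s, pool_seed = 7500 + s)
    cfgB <- cfgA; cfgB$seed <- 8000 + s
    dA <- generate_scenario(cfgA)
    dB <- generate_scenario(cfgB)
    mA <- mqtl_pipeline(dA$bundle$genotypes, dA$bundle$methylation,
                        dA$bundle$covariates, dA$bundle$cpg_info)
    if (!nrow(mA)) next
    top <- mA[which.min(mA$p), ]
    mB <- mqtl_pipeline(dB$bundle$genotypes, dB$bundle$methylation,
                        dB$bundle$covariates, dB$bundle$cpg_info,
                        p_threshold = 1)
    out <- replication_check(
      data.frame(cpg_id = top$cpg_id, snp_id = top$snp_id,
                 beta = top$beta, p = top$p),
      data.frame(cpg_id = mB$cpg_id, snp_id = mB$snp_id,
                 beta = mB$beta, p = mB$p))
    tested <- tested + nrow(out)
    hits <- hits + sum(out$concordant)
  }
  expect_gte(tested, 8)
  expect_gte(hits / tested, 0.9)
})

test_that("cross-tissue correlation uses the Fisher-z interval", {
  # construct vectors with exactly r = 0.5 at n = 30
  set.seed(501)
  x <- rnorm(30)
  e <- residuals(lm(rnorm(30) ~ x))
  xs <- drop(scale(x)); es <- drop(scale(e))
  y <- 0.5 * xs + sqrt(0.75) * es
  res <- cross_tissue_correlation(xs, y)
  expect_equal(res$r, 0.5, tolerance = 1e-10)
  expect_equal(res$ci_low, tanh(atanh(0.5) - 1.96 / sqrt(27)),
               tolerance = 1e-3)
  expect_equal(round(c(res$ci_low, res$ci_high), 2), c(0.17, 0.73))

  ident <- cross_tissue_correlation(xs, xs)
  expect_identical(ident$r, 1)
  expect_identical(ident$ci_low, 1)

  expect_error(cross_tissue_correlation(rep(1, 10), rnorm(10)), "variance")
  expect_error(cross_tissue_correlation(1:3, 1:3), "4 complete")
})

test_that("subtype ANOVA matches the textbook one-way F and detects
          separation", {
  set.seed(511)
  y <- rnorm(90)
  g <- rep(c("CLO", "CLP", "CPO"), each = 30)
  res <- subtype_anova(y, g)
  ref <- anova(lm(y ~ factor(g)))
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  y_sep <- c(rnorm(30, 0, 0.01), rnorm(30, 0, 0.01), rnorm(30, 1, 0.01))
  expect_lt(subtype_anova(y_sep, g)$p, 1e-6)

  # covariate adjustment: the F-test conditions on the covariate model
  covs <- data.frame(sex = rbinom(90, 1, 0.5), sv1 = rnorm(90))
  y_adj <- y + 2 * covs$sv1
  res_adj <- subtype_anova(y_adj, g, covs)
  full <- lm(y_adj ~ covs$sex + covs$sv1 + factor(g))
  red <- lm(y_adj ~ covs$sex + covs$sv1)
  ref_adj <- anova(red, full)
  expect_equal(res_adj$F, ref_adj$F[2], tolerance = 1e-10)

  expect_error(subtype_anova(y, rep("A", 90)), "2 subtype groups")
})

test_that("reports round-trip through the formatted TSV", {
  calls <- list(
    classify_locus(fake_mr(1e-8, beta = -1.1, se = 0.2),
                   fake_mr(0.59, beta = 0.04, se = 0.07,
                           direction = "reverse"),
                   fake_coloc(1, stat = -8.5),
                   triangulation_thresholds(forward = 7.8e-6),
                   cpg_id = "cg0001", snp_id = "snp_0001"),
    classify_locus(fake_mr(1e-8, beta = 0.4, se = 0.1),
                   fake_mr(0.6, direction = "reverse"),
                   methtri:::coloc_sentinel("window too sparse"),
                   triangulation_thresholds(forward = 7.8e-6),
                   cpg_id = "cg0002", snp_id = "snp_0002"))
  tmp <- tempfile(fileext = ".tsv")
  build_report(calls, file = tmp, metadata = list(seed = 1))
  expect_true(file.exists(paste0(tmp, ".meta.json")))
  back <- read_report(tmp)
  expect_identical(back$label,
                   c("linkage", "indeterminate"))
  expect_equal(back$forward_beta, c(-1.1, 0.4))
  expect_equal(back$coloc_statistic, c(-8.5, NA))
  expect_identical(back$coloc[2] %||% "NA", "NA")

  # empty input: header-only table
  empty <- build_report(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("snp_id", "cpg_id", "label") %in% names(empty)))
})
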