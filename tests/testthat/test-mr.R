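# Harmonization, Wald ratio, IVW, correlated-instrument GLS, reverse MR,
# Bonferroni thresholds.

test_that("harmonization aligns, flips and drops instruments correctly", {
  exp_s <- rbind(ss_row("rs1", 0.5, 0.05),
                 ss_row("rs2", 0.4, 0.05, ea = "T", oa = "C"),
                 ss_row("rs3", 0.3, 0.05, ea = "A", oa = "T", eaf = 0.5))
  out_s <- rbind(ss_row("rs1", 0.2, 0.04),                       # identical
                 ss_row("rs2", 0.1, 0.04, ea = "C", oa = "T"),   # swapped
                 ss_row("rs3", 0.1, 0.04, ea = "A", oa = "T", eaf = 0.5))
  inst <- harmonize(exp_s, out_s)
  expect_identical(nrow(inst), 2L)
  expect_equal(inst$beta_outcome[inst$snp_id == "rs1"], 0.2)
  expect_equal(inst$beta_outcome[inst$snp_id == "rs2"], -0.1)
  drops <- attr(inst, "dropped")
  expect_identical(drops$snp_id, "rs3")
  expect_identical(drops$reason, "palindromic-ambiguous")

  # strand flip by complement
  out_flip <- ss_row("rs1", 0.2, 0.04, ea = "T", oa = "C")
  inst2 <- harmonize(exp_s[1, ], out_flip)
  expect_equal(inst2$beta_outcome, 0.2)

  expect_error(harmonize(exp_s[3, ], out_s[3, ]), "no shared instruments")
})

test_that("Wald ratio arithmetic and degenerate cases", {
  inst <- data.frame(snp_id = "rs1", effect_allele = "A",
                     beta_exposure = 0.5, se_exposure = 0.05,
                     beta_outcome = 0.2, se_outcome = 0.05)
  w <- wald_ratio(inst)
  expect_equal(w$beta, 0.4)
  expect_equal(w$se, 0.1)
  expect_identical(w$method, "wald")
  expect_identical(w$n_instruments, 1L)

  inst0 <- inst; inst0$beta_outcome <- 0
  w0 <- wald_ratio(inst0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$p, 1)

  inst_bad <- inst; inst_bad$beta_exposure <- 0
  expect_error(wald_ratio(inst_bad), "non-zero")
})

test_that("IVW equals the zero-intercept weighted regression", {
  set.seed(301)
  k <- 5
  inst <- data.frame(snp_id = sprintf("rs%d", 1:k), effect_allele = "A",
                     beta_exposure = runif(k, 0.2, 0.6),
                     se_exposure = runif(k, 0.02, 0.05),
                     beta_outcome = rnorm(k, 0.1, 0.05),
                     se_outcome = runif(k, 0.02, 0.08))
  res <- ivw(inst)
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  beta_ref <- coef(fit)[[1]]
  se_ref <- sqrt(1 / sum(inst$beta_exposure^2 / inst$se_outcome^2))
  expect_equal(res$beta, beta_ref, tolerance = 1e-10)
  expect_equal(res$se, se_ref, tolerance = 1e-10)

  # single instrument delegates to the Wald ratio
  expect_equal(ivw(inst[1, ])$beta, wald_ratio(inst[1, ])$beta)

  # two identical instruments: same beta, se / sqrt(2)
  two <- rbind(inst[1, ], inst[1, ])
  two$snp_id <- c("a", "b")
  res2 <- ivw(two)
  expect_equal(res2$beta, wald_ratio(inst[1, ])$beta)
  expect_equal(res2$se, wald_ratio(inst[1, ])$se / sqrt(2))
})

test_that("correlated-instrument GLS reduces to IVW at identity LD and is
          the likelihood maximizer", {
  set.seed(311)
  k <- 3
  inst <- data.frame(snp_id = sprintf("rs%d", 1:k), effect_allele = "A",
                     beta_exposure = c(0.5, 0.35, 0.42),
                     se_exposure = rep(0.03, k),
                     beta_outcome = c(0.21, 0.12, 0.18),
                     se_outcome = c(0.05, 0.06, 0.045))
  expect_equal(ivw_correlated(inst, diag(k))$beta, ivw(inst)$beta,
               tolerance = 1e-8)
  expect_equal(ivw_correlated(inst, diag(k))$se, ivw(inst)$se,
               tolerance = 1e-4)

  rho <- matrix(c(1, 0.6, 0.3, 0.6, 1, 0.5, 0.3, 0.5, 1), 3)
  res <- ivw_correlated(inst, rho)

  # independent oracle: numerical maximization of the stated MVN likelihood
  S <- diag(inst$se_outcome)
  omega <- S %*% rho %*% S
  negll <- function(b) {
    r <- inst$beta_outcome - b * inst$beta_exposure
    0.5 * drop(r %*% solve(omega, r))
  }
  opt <- optimize(negll, c(-5, 5), tol = 1e-12)
  expect_equal(res$beta, opt$minimum, tolerance = 1e-6)

  # duplicate instruments in near-perfect LD give no spurious precision
  dup <- rbind(inst[1, ], inst[1, ]); dup$snp_id <- c("a", "b")
  rho_dup <- matrix(c(1, 1 - 1e-6, 1 - 1e-6, 1), 2)
  res_dup <- ivw_correlated(dup, rho_dup)
  expect_equal(res_dup$se, wald_ratio(inst[1, ])$se, tolerance = 0.05)

  # continuity: GLS approaches IVW as the LD matrix approaches identity
  eps_rho <- diag(k); eps_rho[eps_rho == 0] <- 1e-5
  expect_equal(ivw_correlated(inst, eps_rho)$beta, ivw(inst)$beta,
               tolerance = 1e-4)
})

test_that("MR estimates are scale and sign equivariant", {
  set.seed(321)
  k <- 4
  inst <- data.frame(snp_id = sprintf("rs%d", 1:k), effect_allele = "A",
                     beta_exposure = runif(k, 0.3, 0.6),
                     se_exposure = rep(0.03, k),
                     beta_outcome = rnorm(k, 0.2, 0.02),
                     se_outcome = runif(k, 0.03, 0.06))
  base <- ivw(inst)

  scaled <- inst
  scaled$beta_exposure <- inst$beta_exposure * 2.5
  expect_equal(ivw(scaled)$beta, base$beta / 2.5, tolerance = 1e-12)

  # flipping the reported effect allele of one instrument (both betas
  # negated) leaves the estimate unchanged
  flipped <- inst
  flipped$beta_exposure[2] <- -flipped$beta_exposure[2]
  flipped$beta_outcome[2] <- -flipped$beta_outcome[2]
  expect_equal(ivw(flipped)$beta, base$beta, tolerance = 1e-12)

  rho <- diag(k); rho[1, 2] <- rho[2, 1] <- 0.4
  base_ld <- ivw_correlated(inst, rho)
  flip_ld <- ivw_correlated(flipped, rho * outer(c(1, -1, 1, 1),
                                                 c(1, -1, 1, 1)))
  expect_equal(flip_ld$beta, base_ld$beta, tolerance = 1e-10)
})

test_that("reverse MR is labelled and reduces to a Wald ratio for one SNP", {
  dis <- rbind(ss_row("rs1", 0.4, 0.05), ss_row("rs2", 0.3, 0.05,
                                                pos = 2000L))
  meth <- rbind(ss_row("rs1", 0.1, 0.04), ss_row("rs2", 0.08, 0.04,
                                                 pos = 2000L))
  res <- reverse_mr(dis, meth)
  expect_identical(res$direction, "reverse")
  expect_identical(res$method, "ivw")

  one <- reverse_mr(dis[1, ], meth[1, ])
  expect_equal(one$beta, 0.1 / 0.4)
  expect_identical(one$method, "wald")
})

test_that("Bonferroni thresholds", {
  expect_equal(signif(bonferroni_threshold(0.05, 6425), 2), 7.8e-6)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})
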