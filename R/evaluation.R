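# Self-evaluation studies: type-I-error calibration of every test in the
# pipeline, parameter recovery for the forward MR, and end-to-end
# causal-model discrimination. These are the simulation experiments the
# package uses to validate itself; the acceptance script and the test
# suite both run them. Replicate counts are sized so the whole battery
# runs on one CPU in minutes; the Monte-Carlo bands quoted in the tests
# correspond to these counts.

#' Type-I error of the trio TDT under the null
#'
#' Simulates affected-offspring trios under the null model (no genetic
#' disease effects), runs the TDT at one SNP per replicate, and returns the
#' rejection rate at `alpha`.
#'
#' @param n_reps replicates.
#' @param n_trios trios per replicate.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate`, `n_reps`.
#' @export
eval_tdt_type1 <- function(n_reps = 500, n_trios = 100, alpha = 0.05,
                           seed = 1) {
  pool <- make_haplotype_pool(4, 0.25, 0.35, block_sizes = rep(1, 4),
                              pool_size = 1000, seed = seed)
  cfg <- scenario_config("null", mqtl_effect = 0, prevalence = 0.1,
                         seed = seed)
  rej <- vapply(seq_len(n_reps), function(r) {
    tr <- simulate_trios(pool, cfg, n_trios, causal_snp_index = 1,
                         seed = seed + 7 * r)
    cnt <- tdt_counts(tr, "snp_0001")
    tdt_test(cnt$b, cnt$c)$p < alpha
  }, NA)
  list(rate = mean(rej), n_reps = n_reps)
}

#' Type-I error of the case-control logistic association under the null
#'
#' One cohort with `n_snps` mutually independent SNPs and a
#' liability-threshold phenotype carrying no genetic effect; each SNP is an
#' independent null test.
#'
#' @param n_snps SNP-level null tests.
#' @param n_individuals cohort size.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate`, `n_reps`.
#' @export
eval_casecontrol_type1 <- function(n_snps = 500, n_individuals = 1500,
                                   alpha = 0.05, seed = 1) {
  pool <- make_haplotype_pool(n_snps, 0.1, 0.4,
                              block_sizes = rep(1, n_snps),
                              pool_size = 1000, seed = seed)
  panel <- draw_genotypes(pool, n_individuals, seed = seed + 1)
  cfg <- scenario_config("null", mqtl_effect = 0, prevalence = 0.1,
                         seed = seed)
  dis <- simulate_disease(panel, rep(0, n_individuals), cfg,
                          causal_snp_index = 1, seed = seed + 2)
  res <- case_control_assoc(panel, dis$phenotype)
  list(rate = mean(res$p < alpha), n_reps = nrow(res))
}

#' Reverse-MR specificity under mediation and power under reverse causation
#'
#' Each replicate draws a methylation cohort and an independent disease
#' cohort from a common population, estimates the six background disease
#' SNPs' effects on disease (logistic) and on the focal CpG's normalized
#' methylation (cis scan), and combines them by IVW with liability as the
#' exposure. Under mediation the CpG is driven by its own mQTL only, so
#' the reverse test is null; under reverse causation it is driven by the
#' polygenic liability and the test should reject.
#'
#' The first-order Wald/IVW standard error assumes strong instruments; the
#' default disease cohort size is chosen so the instruments reach
#' genome-wide-significant strength (z around 6), the regime the method
#' targets — with markedly weaker instruments the first-order test is
#' mildly anticonservative.
#'
#' @param model `"mediation"` (specificity) or `"reverse_causation"`
#'   (power).
#' @param n_reps replicates.
#' @param n_meth,n_disease cohort sizes.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate` (rejection fraction), `n_reps`.
#' @export
eval_reverse_mr <- function(model = "mediation", n_reps = 500,
                            n_meth = 800, n_disease = 2500, alpha = 0.05,
                            seed = 1) {
  rej <- vapply(seq_len(n_reps), function(r) {
    base <- seed + 1000 * r
    dm <- generate_scenario(scenario_config(
      model, n_individuals = n_meth, n_trios = 0, pool_size = 1000,
      seed = base + 1, pool_seed = base))
    dd <- generate_scenario(scenario_config(
      model, n_individuals = n_disease, n_trios = 0, pool_size = 1000,
      seed = base + 2, pool_seed = base))
    bm <- dm$bundle
    m_res <- residualize(
      inverse_normal_transform(bm$methylation[, 1]), bm$covariates)
    scan <- cis_scan(bm$genotypes, m_res, bm$cpg_info[1, , drop = FALSE],
                     p_threshold = 1)
    bg <- dd$truth_table$snp_id[dd$truth_table$role == "background_disease"]
    dis_exp <- case_control_assoc(dd$bundle$genotypes, dd$bundle$phenotype,
                                  snp_ids = bg)
    out_meth <- mqtl_to_summary_stats(
      scan[scan$snp_id %in% dis_exp$snp_id, , drop = FALSE],
      bm$genotypes, n = n_meth)
    reverse_mr(dis_exp, out_meth)$p < alpha
  }, NA)
  list(rate = mean(rej), n_reps = n_reps)
}

#' Type-I error of the covariate-adjusted subtype ANOVA under the null
#'
#' @param n_reps replicates.
#' @param n samples per replicate (three equal groups).
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate`, `n_reps`.
#' @export
eval_anova_type1 <- function(n_reps = 500, n = 150, alpha = 0.05,
                             seed = 1) {
  subtype <- rep(c("CLO", "CLP", "CPO"), length.out = n)
  rej <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    covs <- data.frame(sex = rbinom(n, 1, 0.5), sv1 = rnorm(n),
                       sv2 = rnorm(n))
    y <- rnorm(n) + 0.3 * covs$sv1
    subtype_anova(y, subtype, covs)$p < alpha
  }, NA))
  list(rate = mean(rej), n_reps = n_reps)
}

#' Colocalization rejection rate under the linkage scenario
#'
#' Two distinct causal variants in LD (`r^2 = linkage_r2 <= 0.5`, below
#' the 0.8 resolution limit) drive methylation and disease; rejecting
#' colocalization here would wrongly merge the signals, so the rejection
#' rate at `alpha` measures the test's type-I error for the
#' shared-causal-variant hypothesis.
#'
#' @param n_reps replicates.
#' @param n_perm permutations per replicate.
#' @param n_meth,n_disease cohort sizes.
#' @param linkage_r2 LD between the two causal variants.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate` (among testable windows), `n_reps`,
#'   `n_testable`.
#' @export
eval_jlim_linkage_type1 <- function(n_reps = 500, n_perm = 200,
                                    n_meth = 800, n_disease = 1500,
                                    linkage_r2 = 0.5, alpha = 0.05,
                                    seed = 1) {
  p <- vapply(seq_len(n_reps), function(r) {
    base <- seed + 1000 * r
    dm <- generate_scenario(scenario_config(
      "linkage", n_individuals = n_meth, n_trios = 0, pool_size = 1000,
      linkage_r2 = linkage_r2, seed = base + 1, pool_seed = base))
    dd <- generate_scenario(scenario_config(
      "linkage", n_individuals = n_disease, n_trios = 0, pool_size = 1000,
      linkage_r2 = linkage_r2, seed = base + 2, pool_seed = base))
    bm <- dm$bundle
    m_res <- residualize(
      inverse_normal_transform(bm$methylation[, 1]), bm$covariates)
    scan <- cis_scan(bm$genotypes, m_res, bm$cpg_info[1, , drop = FALSE],
                     p_threshold = 1)
    res <- coloc_step(bm$genotypes, scan, m_res, dd$bundle$genotypes,
                      dd$bundle$phenotype, bm$cpg_info[1, , drop = FALSE],
                      n_permutations = n_perm, seed = base + 3)
    if (res$sentinel) NA_real_ else res$p_permutation
  }, 0)
  list(rate = mean(p < alpha, na.rm = TRUE), n_reps = n_reps,
       n_testable = sum(!is.na(p)))
}

#' Forward-MR recovery of the methylation-to-liability effect
#'
#' The generative effect is on the liability scale while the MR estimate is
#' a log odds ratio per SD methylation, so the recovery target is the
#' attenuated truth: the ratio of the logistic SNP-disease coefficient to
#' the linear SNP-methylation coefficient in one very large cohort (the
#' oracle). Each replicate then runs the discovery pipeline (scan, clump,
#' Wald ratio against an independent case-control cohort) and the median
#' estimate is compared with the oracle.
#'
#' @param n_reps replicates.
#' @param n_meth,n_disease cohort sizes per replicate.
#' @param n_oracle size of the attenuation oracle cohort.
#' @param seed RNG seed.
#' @return list with `median_estimate`, `attenuated_truth`,
#'   `recovery_ratio` (median / truth), `attenuation_factor`
#'   (truth / liability-scale effect), `n_reps`.
#' @export
eval_forward_recovery <- function(n_reps = 200, n_meth = 1000,
                                  n_disease = 2000, n_oracle = 3e5,
                                  seed = 1) {
  cfg_oracle <- scenario_config("mediation", n_individuals = n_oracle,
                                n_trios = 0, pool_size = 2000,
                                seed = seed, pool_seed = seed)
  big <- generate_scenario(cfg_oracle)
  g <- big$bundle$genotypes$dosage[, big$indices$causal_snp]
  m_std <- drop(scale(big$bundle$methylation_latent[, 1]))
  b_gd <- coef(glm(big$bundle$phenotype ~ g, family = binomial()))[["g"]]
  b_gm <- coef(lm(m_std ~ g))[["g"]]
  truth <- b_gd / b_gm

  est <- vapply(seq_len(n_reps), function(r) {
    base <- seed + 1000 * r
    dm <- generate_scenario(scenario_config(
      "mediation", n_individuals = n_meth, n_trios = 0, pool_size = 1000,
      seed = base + 1, pool_seed = base))
    dd <- generate_scenario(scenario_config(
      "mediation", n_individuals = n_disease, n_trios = 0,
      pool_size = 1000, seed = base + 2, pool_seed = base))
    bm <- dm$bundle
    mqtl <- mqtl_pipeline(bm$genotypes, bm$methylation, bm$covariates,
                          bm$cpg_info[1, , drop = FALSE])
    if (!nrow(mqtl)) return(NA_real_)
    exp_stats <- mqtl_to_summary_stats(mqtl, bm$genotypes, n = n_meth)
    idx <- clump(exp_stats, bm$genotypes)
    exp_stats <- exp_stats[match(idx, exp_stats$snp_id), , drop = FALSE]
    out_stats <- case_control_assoc(dd$bundle$genotypes,
                                    dd$bundle$phenotype, snp_ids = idx)
    inst <- harmonize(exp_stats, out_stats)
    mr_forward(inst)$beta
  }, 0)
  med <- median(est, na.rm = TRUE)
  list(median_estimate = med, attenuated_truth = truth,
       recovery_ratio = med / truth,
       attenuation_factor = truth / cfg_oracle$methylation_to_liability,
       n_reps = n_reps, n_estimable = sum(!is.na(est)))
}

#' End-to-end causal-model discrimination accuracy
#'
#' Runs the full per-locus pipeline over simulated loci with known causal
#' structure and tabulates how often the classifier assigns the generating
#' model's label (mediation and pleiotropy both map to
#' `putative_mediation_or_pleiotropy`).
#'
#' @param n_per_model loci per causal model.
#' @param models causal models to include.
#' @param n_perm colocalization permutations per locus.
#' @param n_meth,n_disease cohort sizes.
#' @param seed RNG seed.
#' @return list with per-model `accuracy`, the full `labels` table and
#'   `n_per_model`.
#' @export
eval_discrimination <- function(n_per_model = 50,
                                models = c("mediation", "linkage",
                                           "reverse_causation",
                                           "pleiotropy"),
                                n_perm = 200, n_meth = 1000,
                                n_disease = 2000, seed = 1) {
  expected <- c(mediation = "putative_mediation_or_pleiotropy",
                pleiotropy = "putative_mediation_or_pleiotropy",
                linkage = "linkage",
                reverse_causation = "reverse_causation",
                null = "no_signal")
  labels <- list()
  accuracy <- numeric(0)
  off <- 0
  for (model in models) {
    lab <- vapply(seq_len(n_per_model), function(r) {
      base <- seed + 1000 * (off + r)
      dm <- generate_scenario(scenario_config(
        model, n_individuals = n_meth, n_trios = 0, pool_size = 1000,
        seed = base + 1, pool_seed = base))
      dd <- generate_scenario(scenario_config(
        model, n_individuals = n_disease, n_trios = 0, pool_size = 1000,
        seed = base + 2, pool_seed = base))
      triangulate_locus(dm, dd, n_permutations = n_perm,
                        seed = base + 3)$label
    }, "")
    labels[[model]] <- lab
    accuracy[model] <- mean(lab == expected[[model]])
    off <- off + n_per_model
  }
  list(accuracy = accuracy, labels = labels, n_per_model = n_per_model)
}
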