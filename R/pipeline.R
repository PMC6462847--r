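# End-to-end per-locus driver: from two cohorts (a methylation cohort and a
# disease case-control cohort drawn from the same population, the
# two-sample MR design) to a triangulated causal-model call.

mr_na_result <- function(direction, reason = "not estimable") {
  out <- data.frame(exposure = NA_character_, outcome = NA_character_,
                    method = NA_character_, n_instruments = 0L,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "reason") <- reason
  out
}

#' Colocalization stage of the pipeline
#'
#' Finds the disease lead SNP near the CpG, builds the z-score window
#' around it (disease z from case-control regression, methylation z from
#' the cis scan, LD from the methylation cohort), and runs the
#' permutation-calibrated joint-likelihood test. Returns the sparse-window
#' sentinel when fewer than two usable SNPs remain.
#'
#' @param panel_m,panel_d methylation- and disease-cohort genotype panels.
#' @param scan_all full cis-scan records for the CpG (`p_threshold = 1`).
#' @param m_res residualized, normalized methylation vector.
#' @param phenotype disease status for the disease cohort.
#' @param cpg_info one-row CpG table.
#' @param n_permutations,coloc_window_bp,r2_resolution,seed as in
#'   [triangulate_locus()].
#' @return a `coloc_result`.
#' @export
coloc_step <- function(panel_m, scan_all, m_res, panel_d, phenotype,
                       cpg_info, n_permutations = 200,
                       coloc_window_bp = 1e5, r2_resolution = 0.8,
                       seed = 1) {
  region <- panel_d$snp_info[
    panel_d$snp_info$chrom == cpg_info$chrom &
      abs(panel_d$snp_info$pos - cpg_info$pos) <= 2.5e5, , drop = FALSE]
  if (nrow(region) < 2) {
    return(coloc_sentinel("fewer than two SNPs near the CpG"))
  }
  region_stats <- case_control_assoc(panel_d, phenotype,
                                     snp_ids = region$snp_id)
  if (nrow(region_stats) < 2) {
    return(coloc_sentinel("no disease association computable in the region"))
  }
  lead <- region_stats[which.min(region_stats$p), ]
  win <- region_stats[abs(region_stats$pos - lead$pos) <= coloc_window_bp, ,
                      drop = FALSE]
  win <- win[win$snp_id %in% scan_all$snp_id, , drop = FALSE]
  if (nrow(win) < 2) {
    return(coloc_sentinel("window too sparse after matching the two scans"))
  }
  z1 <- win$beta / win$se
  scan_win <- scan_all[match(win$snp_id, scan_all$snp_id), ]
  z2 <- scan_win$beta / scan_win$se
  R <- compute_ld(panel_m, win$snp_id)
  window <- coloc_window(win$snp_id, z1, z2, R,
                         r2_resolution = r2_resolution)
  jlim_permutation_p(window, panel_m, m_res,
                     n_permutations = n_permutations, seed = seed)
}

#' Run the full triangulation pipeline at one locus
#'
#' Given a methylation cohort and an independent disease case-control
#' cohort (two [generate_scenario()] objects built from the same scenario
#' with different seeds, or equivalent user data), runs: cis-mQTL discovery
#' (inverse-normal transform, covariate residualization, windowed scan at
#' `p < mqtl_p_threshold`), LD clumping of the discovered mQTL, forward MR
#' (Wald ratio, or the correlated-instrument GLS when several instruments
#' survive clumping), reverse MR using the known independent disease risk
#' SNPs as instruments, joint-likelihood colocalization with permutation
#' significance in a window around the disease lead SNP, and the
#' decision-table classifier.
#'
#' @param meth_data `scenario_data` providing genotypes, methylation and
#'   covariates (the mQTL cohort; its genotypes double as the LD
#'   reference).
#' @param disease_data `scenario_data` providing genotypes and phenotype
#'   (the GWAS cohort).
#' @param disease_snp_ids SNP ids of the independent, genome-wide
#'   significant disease variants used as reverse-MR instruments; defaults
#'   to the background disease SNPs recorded in the disease cohort's truth
#'   table.
#' @param n_permutations colocalization permutations.
#' @param thresholds [triangulation_thresholds()].
#' @param mqtl_p_threshold cis-mQTL emission threshold (default 1e-7).
#' @param clump_r2,clump_window_kb clumping parameters (defaults 0.001 and
#'   250).
#' @param coloc_window_bp half-width of the colocalization window around the
#'   disease lead SNP (default 100 kb).
#' @param r2_resolution colocalization genetic-resolution limit.
#' @param seed RNG seed for the permutation stage.
#' @return a [classify_locus()] `triangulation_call`; the `components`
#'   attribute carries the intermediate mQTL records, instruments and
#'   summary statistics.
#' @export
triangulate_locus <- function(meth_data, disease_data,
                              disease_snp_ids = NULL,
                              n_permutations = 200,
                              thresholds = triangulation_thresholds(),
                              mqtl_p_threshold = 1e-7,
                              clump_r2 = 0.001, clump_window_kb = 250,
                              coloc_window_bp = 1e5, r2_resolution = 0.8,
                              seed = 1) {
  bm <- meth_data$bundle
  bd <- disease_data$bundle
  panel_m <- bm$genotypes
  panel_d <- bd$genotypes
  cpg_info <- bm$cpg_info[1, , drop = FALSE]
  cpg_id <- cpg_info$cpg_id

  # normalized, residualized methylation (used by scan and permutations)
  m_int <- inverse_normal_transform(bm$methylation[, cpg_id])
  m_res <- residualize(m_int, bm$covariates)

  # cis associations at every SNP (p_threshold = 1), thresholded for
  # discovery below; keeps one scan pass for mQTL, reverse outcome and z2
  scan_all <- cis_scan(panel_m, m_res, cpg_info, p_threshold = 1)
  mqtl <- scan_all[scan_all$p < mqtl_p_threshold, , drop = FALSE]

  forward <- mr_na_result("forward", "no significant cis-mQTL")
  instruments <- NULL
  snp_id <- NA_character_
  if (nrow(mqtl) > 0) {
    exp_stats <- mqtl_to_summary_stats(mqtl, panel_m, n = nrow(panel_m$dosage))
    idx <- clump(exp_stats, panel_m, r2_threshold = clump_r2,
                 window_kb = clump_window_kb)
    exp_stats <- exp_stats[match(idx, exp_stats$snp_id), , drop = FALSE]
    out_stats <- case_control_assoc(panel_d, bd$phenotype, snp_ids = idx)
    forward <- tryCatch({
      instruments <- harmonize(exp_stats, out_stats,
                               exposure_name = cpg_id,
                               outcome_name = "disease")
      ld <- if (nrow(instruments) > 1) {
        compute_ld(panel_m, instruments$snp_id)
      } else NULL
      mr_forward(instruments, ld)
    }, error = function(e) mr_na_result("forward", conditionMessage(e)))
    snp_id <- idx[1]
  }

  if (is.null(disease_snp_ids)) {
    tt <- disease_data$truth_table
    disease_snp_ids <- tt$snp_id[tt$role == "background_disease"]
  }
  reverse <- mr_na_result("reverse", "no disease instruments")
  if (length(disease_snp_ids)) {
    reverse <- tryCatch({
      dis_exp <- case_control_assoc(panel_d, bd$phenotype,
                                    snp_ids = disease_snp_ids)
      scan_bg <- scan_all[scan_all$snp_id %in% dis_exp$snp_id, , drop = FALSE]
      out_meth <- mqtl_to_summary_stats(scan_bg, panel_m,
                                        n = nrow(panel_m$dosage))
      reverse_mr(dis_exp, out_meth, outcome_name = cpg_id)
    }, error = function(e) mr_na_result("reverse", conditionMessage(e)))
  }

  coloc <- coloc_step(panel_m, scan_all, m_res, panel_d, bd$phenotype,
                      cpg_info, n_permutations = n_permutations,
                      coloc_window_bp = coloc_window_bp,
                      r2_resolution = r2_resolution, seed = seed)

  call <- classify_locus(forward, reverse, coloc, thresholds,
                         cpg_id = cpg_id, snp_id = snp_id)
  attr(call, "components") <- list(mqtl = mqtl, instruments = instruments,
                                   scan = scan_all)
  call
}
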