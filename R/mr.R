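# Bidirectional two-sample Mendelian randomization: instrument
# harmonization, Wald ratio, inverse-variance weighting, and a
# correlated-instrument generalized-least-squares estimator for CpGs whose
# instruments are in residual LD.

#' Harmonize exposure and outcome summary statistics into an instrument set
#'
#' Restricts to shared SNPs and aligns the outcome records to the exposure's
#' effect-allele orientation: swapped alleles flip the outcome beta, strand
#' flips are resolved by complement, and palindromic SNPs (A/T, C/G) are
#' dropped when effect-allele frequency is missing or in `[0.42, 0.58]` on
#' either side. A drop log is kept in the `dropped` attribute.
#'
#' @param exposure_stats,outcome_stats SummaryStats data.frames.
#' @param exposure_name,outcome_name labels carried into MR results.
#' @return object of class `instrument_set`: data.frame with `snp_id`,
#'   `effect_allele`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @export
harmonize <- function(exposure_stats, outcome_stats,
                      exposure_name = "exposure", outcome_name = "outcome") {
  shared <- intersect(exposure_stats$snp_id, outcome_stats$snp_id)
  dropped <- list()
  rows <- list()
  for (id in shared) {
    e <- exposure_stats[match(id, exposure_stats$snp_id), ]
    o <- outcome_stats[match(id, outcome_stats$snp_id), ]
    act <- harmonize_alleles(e$effect_allele, e$other_allele,
                             o$effect_allele, o$other_allele,
                             e$eaf, o$eaf)
    if (act %in% c("drop_palindromic", "drop_mismatch")) {
      reason <- if (act == "drop_palindromic") "palindromic-ambiguous"
                else "allele-mismatch"
      dropped[[length(dropped) + 1L]] <- data.frame(snp_id = id,
                                                    reason = reason)
      next
    }
    sign <- if (act %in% c("swap", "flip_swap")) -1 else 1
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = id, effect_allele = e$effect_allele,
      beta_exposure = e$beta, se_exposure = e$se,
      beta_outcome = sign * o$beta, se_outcome = o$se,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out) || nrow(out) == 0) {
    stop("no shared instruments remain after harmonization")
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                          else data.frame(snp_id = character(0),
                                          reason = character(0))
  attr(out, "exposure") <- exposure_name
  attr(out, "outcome") <- outcome_name
  class(out) <- c("instrument_set", class(out))
  out
}

mr_result <- function(exposure, outcome, method, n_instruments, beta, se,
                      direction) {
  data.frame(exposure = exposure, outcome = outcome, method = method,
             n_instruments = as.integer(n_instruments),
             beta = beta, se = se, p = normal_p(beta, se),
             direction = direction, stringsAsFactors = FALSE)
}

#' Single-instrument Wald ratio
#'
#' `beta = beta_outcome / beta_exposure` with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (no exposure-uncertainty
#' term, standard two-sample practice with strong instruments); two-sided
#' normal p.
#'
#' @param instruments one-row [harmonize()] instrument set (or a data.frame
#'   with the same columns).
#' @param direction `"forward"` or `"reverse"` label.
#' @return one-row MR result data.frame (`exposure`, `outcome`, `method`,
#'   `n_instruments`, `beta`, `se`, `p`, `direction`).
#' @export
wald_ratio <- function(instruments, direction = "forward") {
  stopifnot(nrow(instruments) == 1)
  bx <- instruments$beta_exposure
  if (bx == 0) stop("beta_exposure must be non-zero for a Wald ratio")
  mr_result(attr(instruments, "exposure") %||% "exposure",
            attr(instruments, "outcome") %||% "outcome",
            "wald", 1L,
            instruments$beta_outcome / bx,
            instruments$se_outcome / abs(bx), direction)
}

#' Inverse-variance-weighted MR
#'
#' Combines per-instrument Wald ratios with weights `1/se_j^2` where
#' `se_j = se_outcome_j / |beta_exposure_j|`; algebraically identical to a
#' zero-intercept regression of outcome betas on exposure betas weighted by
#' `1/se_outcome^2`, with the fixed-effect standard error. A single
#' instrument reduces exactly to [wald_ratio()].
#'
#' @inheritParams wald_ratio
#' @return one-row MR result data.frame.
#' @export
ivw <- function(instruments, direction = "forward") {
  if (nrow(instruments) == 1) return(wald_ratio(instruments, direction))
  if (any(instruments$beta_exposure == 0)) {
    stop("beta_exposure must be non-zero for every instrument")
  }
  ratio <- instruments$beta_outcome / instruments$beta_exposure
  se_r <- instruments$se_outcome / abs(instruments$beta_exposure)
  w <- 1 / se_r^2
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  mr_result(attr(instruments, "exposure") %||% "exposure",
            attr(instruments, "outcome") %||% "outcome",
            "ivw", nrow(instruments), beta, se, direction)
}

#' Correlated-instrument MR by generalized least squares
#'
#' For instruments in LD the independent-weight IVW overstates precision.
#' With `x` the exposure betas, `y` the outcome betas, `S = diag(se_outcome)`
#' and `rho` the signed LD correlation matrix of the instruments, the
#' estimator is the GLS solution `beta = (x' Omega^-1 x)^-1 x' Omega^-1 y`
#' with `Omega = S rho S` and `se = sqrt((x' Omega^-1 x)^-1)`. This is the
#' maximizer of the multivariate-normal likelihood `y ~ MVN(beta x, Omega)`,
#' and reduces to [ivw()] when `rho` is the identity. `rho` must be the
#' signed correlation (not r-squared). The LD matrix is ridge-stabilized
#' (`+1e-6` on the diagonal) before inversion.
#'
#' @inheritParams wald_ratio
#' @param ld signed LD correlation matrix covering all instruments
#'   (dimnames matched against `snp_id` when present).
#' @param ridge diagonal stabilizer.
#' @return one-row MR result data.frame with method `"ivw_ld"`.
#' @export
ivw_correlated <- function(instruments, ld, direction = "forward",
                           ridge = 1e-6) {
  k <- nrow(instruments)
  if (!is.null(dimnames(ld))) {
    miss <- setdiff(instruments$snp_id, rownames(ld))
    if (length(miss)) stop("LD matrix missing instrument(s): ",
                           paste(miss, collapse = ", "))
    ld <- ld[instruments$snp_id, instruments$snp_id, drop = FALSE]
  }
  stopifnot(nrow(ld) == k, ncol(ld) == k)
  x <- instruments$beta_exposure
  y <- instruments$beta_outcome
  S <- instruments$se_outcome
  omega <- (S %o% S) * ld_ridge(ld, ridge)
  oi <- tryCatch(solve(omega), error = function(e) {
    stop("LD-weighted covariance is singular even after ridge stabilization")
  })
  xox <- drop(t(x) %*% oi %*% x)
  beta <- drop(t(x) %*% oi %*% y) / xox
  se <- sqrt(1 / xox)
  mr_result(attr(instruments, "exposure") %||% "exposure",
            attr(instruments, "outcome") %||% "outcome",
            "ivw_ld", k, beta, se, direction)
}

#' Forward MR dispatcher
#'
#' Applies the paper-style rule: one instrument, Wald ratio; several
#' independent instruments, IVW; several instruments with an LD matrix,
#' the correlated-instrument GLS re-test.
#'
#' @inheritParams ivw_correlated
#' @export
mr_forward <- function(instruments, ld = NULL) {
  if (nrow(instruments) == 1) return(wald_ratio(instruments, "forward"))
  if (is.null(ld)) ivw(instruments, "forward")
  else ivw_correlated(instruments, ld, "forward")
}

#' Reverse MR: genetic liability as exposure, methylation as outcome
#'
#' Tests reverse causation by instrumenting disease liability with
#' independent (clumped) genome-wide-significant disease SNPs and taking
#' SNP-methylation associations as the outcome, combined by IVW.
#'
#' @param disease_instruments SummaryStats for the disease SNPs (exposure).
#' @param mqtl_outcome_stats SummaryStats of the same SNPs' effects on
#'   methylation at one CpG.
#' @param exposure_name,outcome_name labels.
#' @return one-row MR result with `direction = "reverse"`.
#' @export
reverse_mr <- function(disease_instruments, mqtl_outcome_stats,
                       exposure_name = "disease_liability",
                       outcome_name = "methylation") {
  inst <- harmonize(disease_instruments, mqtl_outcome_stats,
                    exposure_name, outcome_name)
  ivw(inst, direction = "reverse")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (`>= 1`).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}

#' Attach allele and frequency metadata to mQTL records
#'
#' [cis_scan()] records carry no allele labels; this joins them against a
#' panel's SNP table so they can be harmonized as MR exposure statistics.
#'
#' @param records mQTL records for a single CpG.
#' @param panel genotype panel whose `snp_info` supplies alleles; effect
#'   allele frequency is computed from its dosages.
#' @param n sample size of the mQTL study.
#' @return SummaryStats data.frame.
#' @export
mqtl_to_summary_stats <- function(records, panel, n) {
  i <- match(records$snp_id, panel$snp_info$snp_id)
  if (anyNA(i)) stop("mQTL SNP(s) absent from panel: ",
                     paste(records$snp_id[is.na(i)], collapse = ", "))
  summary_stats(records$snp_id, panel$snp_info$chrom[i],
                panel$snp_info$pos[i],
                panel$snp_info$effect_allele[i],
                panel$snp_info$other_allele[i],
                records$beta, records$se, records$p,
                eaf = colMeans(panel$dosage[, records$snp_id,
                                            drop = FALSE]) / 2,
                n = n)
}
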