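# cis-mQTL scanning: rank-based inverse-normal transformation, covariate
# residualization, and a windowed linear-regression scan, mirroring the
# two-stage recipe used by the cord-blood mQTL databases (normalize,
# residualize on sex / 10 ancestry PCs / batch / cell proportions, then
# regress residuals on dosage and keep cis associations below a stringent
# p threshold).

#' Rank-based inverse-normal transformation
#'
#' `qnorm((rank - 0.5) / n)` with average ranks for ties. Removes outliers
#' and makes the scan invariant to any strictly monotone rescaling of the
#' raw methylation values; output has mean ~0 and SD ~1.
#'
#' @param values numeric vector with at least 3 finite values.
#' @return transformed vector (NAs preserved in place).
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) stop("need at least 3 finite values")
  v <- values[ok]
  if (max(v) == min(v)) stop("all values identical: no rank information")
  r <- rank(v, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - 0.5) / length(v))
  out
}

#' Residualize methylation on the covariate design
#'
#' Ordinary least squares residuals of `y` on the covariate design built by
#' the package's rules (batch as treatment-coded dummies with the first
#' level dropped; one cell-proportion column dropped because proportions are
#' compositional). Residuals are orthogonal to every retained column.
#'
#' @param y numeric vector or matrix (columns = CpGs).
#' @param covariates covariate data.frame (see [make_covariates()]).
#' @return residuals with the same shape as `y`.
#' @export
residualize <- function(y, covariates) {
  design <- covariate_design(covariates)
  ym <- as.matrix(y)
  if (is.null(design)) return(sweep(ym, 2, colMeans(ym)))
  X <- cbind(`(Intercept)` = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, ym)
  if (is.vector(y)) setNames(drop(res), names(y)) else res
}

#' Windowed cis-mQTL scan
#'
#' For each CpG, a simple linear regression of the (already normalized and
#' residualized) methylation values on additive dosage is run for every SNP
#' within `window_bp` of the CpG (symmetric window, boundary inclusive at
#' exactly `window_bp`); records with `p < p_threshold` are emitted. SNPs
#' more than 1 Mb away are trans by definition and never tested under the
#' default window.
#'
#' @param panel genotype panel.
#' @param residual_methylation numeric vector or matrix (columns = CpGs) of
#'   normalized, residualized methylation.
#' @param cpg_info data.frame with `cpg_id`, `chrom`, `pos`.
#' @param window_bp cis window half-width in base pairs (default 1e6).
#' @param p_threshold emission threshold (default 1e-7; set to 1 to keep
#'   every cis association, e.g. when building reverse-MR outcome
#'   statistics).
#' @return data.frame of mQTL records: `cpg_id`, `cpg_chrom`, `cpg_pos`,
#'   `snp_id`, `snp_pos`, `distance`, `beta` (normalized-methylation SD per
#'   effect allele), `se`, `p`.
#' @export
cis_scan <- function(panel, residual_methylation, cpg_info,
                     window_bp = 1e6, p_threshold = 1e-7) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  M <- as.matrix(residual_methylation)
  if (is.null(colnames(M))) colnames(M) <- cpg_info$cpg_id
  info <- panel$snp_info
  n <- nrow(M)
  out <- list()
  for (k in seq_len(nrow(cpg_info))) {
    cpg <- cpg_info[k, ]
    insel <- which(info$chrom == cpg$chrom &
                     abs(info$pos - cpg$pos) <= window_bp)
    if (!length(insel)) next
    y <- M[, cpg$cpg_id]
    yc <- y - mean(y)
    syy <- sum(yc^2)
    G <- panel$dosage[, info$snp_id[insel], drop = FALSE]
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    poly <- sxx > 0
    sxy <- colSums(Gc * yc)
    b <- sxy[poly] / sxx[poly]
    s2 <- pmax(syy - b^2 * sxx[poly], 0) / (n - 2)
    se <- sqrt(s2 / sxx[poly])
    p <- 2 * pt(-abs(b / se), df = n - 2)
    keep <- p < p_threshold
    if (!any(keep)) next
    idx <- insel[poly][keep]
    out[[length(out) + 1L]] <- data.frame(
      cpg_id = cpg$cpg_id, cpg_chrom = cpg$chrom, cpg_pos = cpg$pos,
      snp_id = info$snp_id[idx], snp_pos = info$pos[idx],
      distance = abs(info$pos[idx] - cpg$pos),
      beta = b[keep], se = se[keep], p = p[keep],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cpg_id = character(0), cpg_chrom = character(0),
               cpg_pos = integer(0), snp_id = character(0),
               snp_pos = integer(0), distance = integer(0),
               beta = numeric(0), se = numeric(0), p = numeric(0))
  rownames(res) <- NULL
  res
}

#' Remove flagged (problematic) probes from mQTL records
#'
#' Drops records whose `cpg_id` is on a flag list (for example
#' cross-hybridizing probes); the number removed is recorded in the
#' `n_removed` attribute.
#'
#' @param records mQTL records from [cis_scan()].
#' @param flagged_probes character vector of CpG ids to exclude.
#' @return filtered records.
#' @export
filter_probes <- function(records, flagged_probes) {
  keep <- !(records$cpg_id %in% flagged_probes)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Full mQTL recipe: normalize, residualize, scan
#'
#' Convenience wrapper applying [inverse_normal_transform()] per CpG,
#' [residualize()] on the covariates, and [cis_scan()].
#'
#' @inheritParams cis_scan
#' @param methylation beta-value matrix (individuals x CpGs).
#' @param covariates covariate table.
#' @param flagged_probes optional probe flag list.
#' @return mQTL records.
#' @export
mqtl_pipeline <- function(panel, methylation, covariates, cpg_info,
                          window_bp = 1e6, p_threshold = 1e-7,
                          flagged_probes = character(0)) {
  M <- apply(as.matrix(methylation), 2, inverse_normal_transform)
  res <- residualize(M, covariates)
  rec <- cis_scan(panel, res, cpg_info, window_bp = window_bp,
                  p_threshold = p_threshold)
  filter_probes(rec, flagged_probes)
}
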