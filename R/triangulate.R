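# Per-locus causal-model calls combining forward MR, reverse MR and
# colocalization, plus the follow-up replication / cross-tissue / subtype
# statistics.

#' Thresholds for the per-locus decision table
#'
#' @param forward forward-MR p threshold; defaults to the Bonferroni
#'   threshold `alpha / n_cpgs`.
#' @param reverse reverse-MR p threshold (nominal 0.05: deliberately
#'   conservative toward mediation claims).
#' @param coloc colocalization permutation-p threshold.
#' @param alpha,n_cpgs used only to build the default forward threshold.
#' @return named list of thresholds.
#' @export
triangulation_thresholds <- function(forward = NULL, reverse = 0.05,
                                     coloc = 0.05, alpha = 0.05,
                                     n_cpgs = 1) {
  list(forward = forward %||% bonferroni_threshold(alpha, n_cpgs),
       reverse = reverse, coloc = coloc)
}

#' Classify a locus into one of the candidate causal models
#'
#' Decision table, applied in order:
#' \enumerate{
#'   \item forward MR not significant: `no_signal`;
#'   \item forward and reverse both significant: `reverse_causation`
#'     (flagged with a power caveat: the reverse test is typically
#'     underpowered, so absence of this call is weak evidence);
#'   \item colocalization undefined (sparse window sentinel):
#'     `indeterminate`;
#'   \item colocalization significant: `putative_mediation_or_pleiotropy`
#'     (single-instrument MR cannot separate mediation from horizontal
#'     pleiotropy, so the call is never plain "mediation");
#'   \item otherwise: `linkage`.
#' }
#'
#' @param forward,reverse one-row MR result data.frames.
#' @param coloc a `coloc_result` (possibly the sparse-window sentinel).
#' @param thresholds a [triangulation_thresholds()] list.
#' @param cpg_id,snp_id identifiers carried into the call.
#' @return object of class `triangulation_call`: list with `cpg_id`,
#'   `snp_id`, `forward`, `reverse`, `coloc`, `label`, `notes`.
#' @export
classify_locus <- function(forward, reverse, coloc,
                           thresholds = triangulation_thresholds(),
                           cpg_id = NA_character_, snp_id = NA_character_) {
  fw_sig <- is.finite(forward$p) && forward$p < thresholds$forward
  rv_sig <- is.finite(reverse$p) && reverse$p < thresholds$reverse
  co_sentinel <- isTRUE(coloc$sentinel)
  co_sig <- !co_sentinel && is.finite(coloc$p_permutation) &&
    coloc$p_permutation < thresholds$coloc
  notes <- character(0)
  label <- if (!fw_sig) {
    "no_signal"
  } else if (rv_sig) {
    notes <- c(notes, "reverse step is power-limited; interpret with care")
    "reverse_causation"
  } else if (co_sentinel) {
    notes <- c(notes, coloc$reason)
    "indeterminate"
  } else if (co_sig) {
    notes <- c(notes,
               "single-instrument MR cannot separate mediation from pleiotropy")
    "putative_mediation_or_pleiotropy"
  } else {
    "linkage"
  }
  structure(list(cpg_id = cpg_id, snp_id = snp_id, forward = forward,
                 reverse = reverse, coloc = coloc, label = label,
                 notes = notes, thresholds = thresholds),
            class = "triangulation_call")
}

#' Replication concordance check
#'
#' Matches discovery and replication records on `(cpg_id, snp_id)` and
#' flags a pair concordant when the replication effect has the same sign as
#' the discovery effect with replication p < 0.05. Unmatched pairs are
#' dropped and logged in the `dropped` attribute.
#'
#' @param discovery,replication data.frames with columns `cpg_id`, `snp_id`,
#'   `beta`, `p`.
#' @return data.frame (`cpg_id`, `snp_id`, `discovery_beta`,
#'   `replication_beta`, `replication_p`, `concordant`) with a `summary`
#'   attribute of counts.
#' @export
replication_check <- function(discovery, replication) {
  key_d <- paste(discovery$cpg_id, discovery$snp_id)
  key_r <- paste(replication$cpg_id, replication$snp_id)
  m <- match(key_d, key_r)
  dropped <- discovery[is.na(m), c("cpg_id", "snp_id")]
  keep <- !is.na(m)
  rep_rows <- replication[m[keep], ]
  out <- data.frame(cpg_id = discovery$cpg_id[keep],
                    snp_id = discovery$snp_id[keep],
                    discovery_beta = discovery$beta[keep],
                    replication_beta = rep_rows$beta,
                    replication_p = rep_rows$p,
                    stringsAsFactors = FALSE)
  out$concordant <- sign(out$discovery_beta) == sign(out$replication_beta) &
    out$replication_p < 0.05
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "summary") <- c(n_tested = nrow(out),
                            n_concordant = sum(out$concordant),
                            n_dropped = nrow(dropped))
  out
}

#' Cross-tissue methylation correlation with a Fisher-z interval
#'
#' Pearson correlation between paired methylation measurements (for example
#' blood vs lip/palate tissue) with the 95 percent confidence interval
#' `tanh(atanh(r) +- z / sqrt(n - 3))`.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped;
#'   at least 4 complete pairs required).
#' @param conf_level confidence level (default 0.95).
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
cross_tissue_correlation <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the vectors")
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, ci_low = r, ci_high = r, n = n))
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  fz <- atanh(r)
  half <- zcrit / sqrt(n - 3)
  list(r = r, ci_low = tanh(fz - half), ci_high = tanh(fz + half), n = n)
}

#' Covariate-adjusted one-way ANOVA across cleft subtypes
#'
#' Extra-sum-of-squares F-test comparing the linear model
#' `methylation ~ covariates + subtype` against `methylation ~ covariates`,
#' with `(k - 1, n - p_full)` degrees of freedom; used to ask whether mean
#' methylation differs between subtype groups after adjusting for sex and
#' surrogate variables.
#'
#' @param methylation numeric response vector.
#' @param subtype group labels (at least 2 groups with at least 2 members
#'   each).
#' @param covariates optional covariate data.frame (numeric columns and/or
#'   factors).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
subtype_anova <- function(methylation, subtype, covariates = NULL) {
  subtype <- factor(subtype)
  if (nlevels(subtype) < 2 || any(table(subtype) < 2)) {
    stop("need >= 2 subtype groups with >= 2 members each")
  }
  n <- length(methylation)
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    X0 <- cbind(X0, covariate_design(as.data.frame(covariates)))
  }
  Xs <- stats::model.matrix(~ subtype)[, -1, drop = FALSE]
  X1 <- cbind(X0, Xs)
  q0 <- qr(X0); q1 <- qr(X1)
  if (q1$rank < ncol(X1)) stop("rank-deficient design in subtype ANOVA")
  rss0 <- sum(qr.resid(q0, methylation)^2)
  rss1 <- sum(qr.resid(q1, methylation)^2)
  df1 <- nlevels(subtype) - 1
  df2 <- n - ncol(X1)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

fmt_est <- function(beta, se, p) {
  sprintf("%.6g (%.6g); %.6g", beta, se, p)
}

#' Write a results table of triangulation calls
#'
#' Emits a table shaped like the study's main results table: one row per
#' locus with `snp_id`, `cpg_id`, formatted `forward` / `reverse`
#' ("beta (se); p"), `coloc` ("statistic; p", or `NA+` with a footnote code
#' for sparse windows) and the assigned label, plus a JSON metadata sidecar
#' (thresholds, seeds, package version).
#'
#' @param calls list of [classify_locus()] calls.
#' @param file optional TSV path; metadata is written to
#'   `paste0(file, ".meta.json")`.
#' @param metadata named list merged into the JSON sidecar.
#' @return the report data.frame (invisibly when written to file).
#' @export
build_report <- function(calls, file = NULL, metadata = list()) {
  rows <- lapply(calls, function(cl) {
    co <- if (isTRUE(cl$coloc$sentinel)) "NA+"
          else sprintf("%.6g; %.6g", cl$coloc$statistic,
                       cl$coloc$p_permutation)
    data.frame(snp_id = cl$snp_id, cpg_id = cl$cpg_id,
               forward = fmt_est(cl$forward$beta, cl$forward$se,
                                 cl$forward$p),
               reverse = fmt_est(cl$reverse$beta, cl$reverse$se,
                                 cl$reverse$p),
               coloc = co, label = cl$label,
               notes = paste(cl$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), cpg_id = character(0),
               forward = character(0), reverse = character(0),
               coloc = character(0), label = character(0),
               notes = character(0))
  rownames(report) <- NULL
  if (!is.null(file)) {
    write.table(report, file, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- c(list(package = "methtri",
                   version = as.character(utils::packageVersion("methtri")),
                   n_calls = nrow(report),
                   footnotes = c(`NA+` = "window too sparse for colocalization")),
              metadata)
    jsonlite::write_json(meta, paste0(file, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Read a triangulation report back into numeric form
#'
#' Parses the formatted "beta (se); p" and "statistic; p" cells written by
#' [build_report()] so the emitted table round-trips.
#'
#' @param file TSV path.
#' @return data.frame with numeric columns `forward_beta`, `forward_se`,
#'   `forward_p`, `reverse_*`, `coloc_statistic`, `coloc_p` (NA for
#'   sentinel rows) alongside ids, labels and notes.
#' @export
read_report <- function(file) {
  raw <- read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  parse3 <- function(s) {
    m <- regmatches(s, regexec("^(\\S+) \\((\\S+)\\); (\\S+)$", s))[[1]]
    as.numeric(m[2:4])
  }
  parse2 <- function(s) {
    if (s == "NA+") return(c(NA_real_, NA_real_))
    as.numeric(strsplit(s, "; ", fixed = TRUE)[[1]])
  }
  fw <- t(vapply(raw$forward, parse3, numeric(3)))
  rv <- t(vapply(raw$reverse, parse3, numeric(3)))
  co <- t(vapply(raw$coloc, parse2, numeric(2)))
  data.frame(snp_id = raw$snp_id, cpg_id = raw$cpg_id,
             forward_beta = fw[, 1], forward_se = fw[, 2],
             forward_p = fw[, 3],
             reverse_beta = rv[, 1], reverse_se = rv[, 2],
             reverse_p = rv[, 3],
             coloc_statistic = co[, 1], coloc_p = co[, 2],
             label = raw$label, notes = raw$notes,
             stringsAsFactors = FALSE, row.names = NULL)
}
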