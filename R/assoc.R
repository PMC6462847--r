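# GWAS-style summary statistics: trio TDT, case-control logistic
# association, fixed-effects inverse-variance meta-analysis, LD matrices and
# greedy clumping.

SUMMARY_STATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele",
                        "other_allele", "beta", "se", "p", "eaf", "n")

# Assemble and sanity-check a SummaryStats data.frame (exact column order).
summary_stats <- function(snp_id, chrom, pos, effect_allele, other_allele,
                          beta, se, p, eaf = NA_real_, n = NA_real_) {
  if (length(snp_id) == 0) {
    out <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), effect_allele = character(0),
                      other_allele = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), eaf = numeric(0),
                      n = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(snp_id = snp_id, chrom = as.character(chrom),
                    pos = as.integer(pos),
                    effect_allele = effect_allele,
                    other_allele = other_allele,
                    beta = beta, se = se, p = p, eaf = eaf, n = n,
                    stringsAsFactors = FALSE)
  validate_summary_stats(out)
  out
}

validate_summary_stats <- function(x, check_consistency = FALSE) {
  missing_cols <- setdiff(SUMMARY_STATS_COLS, names(x))
  if (length(missing_cols)) {
    stop("summary statistics missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$snp_id)) stop("duplicate snp_id in summary statistics")
  if (any(x$se <= 0, na.rm = TRUE)) stop("se must be > 0")
  if (any(x$p <= 0 | x$p > 1, na.rm = TRUE)) stop("p must be in (0, 1]")
  bad <- !(x$effect_allele %in% c("A", "C", "G", "T")) |
    !(x$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("alleles must be one of A,C,G,T (SNP ",
                     x$snp_id[which(bad)[1]], ")")
  if (check_consistency) {
    pref <- normal_p(x$beta, x$se)
    off <- abs(pref - x$p) / pmax(pref, .Machine$double.xmin)
    if (any(off > 1e-6 & x$p > 1e-300, na.rm = TRUE)) {
      warning("beta/se inconsistent with p under the two-sided normal for ",
              sum(off > 1e-6, na.rm = TRUE), " record(s)")
    }
  }
  invisible(x)
}

#' Transmission and non-transmission counts at one SNP
#'
#' Counts transmissions of the effect allele from heterozygous parents to
#' affected children. Homozygous parents are uninformative. For duos (one
#' parent masked), the observed heterozygous parent contributes only when
#' its transmission is unambiguous given the child genotype (child
#' homozygous); this masking rule slightly under-uses duos and carries a
#' mild allele-frequency bias, so calibration claims in this package are
#' made for complete trios.
#'
#' @param trios a [simulate_trios()] `trio_set` (or a list with `father`,
#'   `mother`, `child` dosage matrices).
#' @param snp_id SNP identifier (column name).
#' @return list with `b` (transmissions), `c` (non-transmissions),
#'   `n_informative` families and `flagged` (`TRUE` when no informative
#'   parent exists; such SNPs are excluded downstream).
#' @export
tdt_counts <- function(trios, snp_id) {
  for (m in c("father", "mother", "child")) {
    if (!snp_id %in% colnames(trios[[m]])) stop("SNP ", snp_id,
                                                " absent from ", m)
  }
  gf <- trios$father[, snp_id]
  gm <- trios$mother[, snp_id]
  gc <- trios$child[, snp_id]
  b <- 0L; c_ <- 0L; informative <- 0L
  complete <- !is.na(gf) & !is.na(gm)
  if (any(complete)) {
    f <- gf[complete]; m <- gm[complete]; ch <- gc[complete]
    h <- (f == 1L) + (m == 1L)              # heterozygous parents
    t_het <- ch - (f == 2L) - (m == 2L)     # effect alleles from het parents
    valid <- h > 0L & t_het >= 0L & t_het <= h
    b <- b + sum(t_het[valid])
    c_ <- c_ + sum(h[valid] - t_het[valid])
    informative <- informative + sum(valid & h > 0L)
  }
  # duos: transmission determined only when the child is homozygous
  duo <- xor(is.na(gf), is.na(gm))
  if (any(duo)) {
    gp <- ifelse(is.na(gf[duo]), gm[duo], gf[duo])
    ch <- gc[duo]
    het <- gp == 1L & (ch == 0L | ch == 2L)
    b <- b + sum(ch[het] == 2L)
    c_ <- c_ + sum(ch[het] == 0L)
    informative <- informative + sum(het)
  }
  list(b = as.integer(b), c = as.integer(c_),
       n_informative = as.integer(informative), flagged = (b + c_) == 0L)
}

#' Transmission disequilibrium test from transmission counts
#'
#' McNemar-type chi-square `(b - c)^2 / (b + c)` on 1 df, with the p-value
#' from the chi-square distribution. For meta-analysis compatibility the
#' record also carries `beta = log(b/c)` and `se = sqrt(1/b + 1/c)`; when
#' either count is zero a Haldane correction of +0.5 is applied to both
#' counts for the log-odds and its SE.
#'
#' @param b,c transmitted / non-transmitted counts (`b + c > 0`).
#' @return list with `chisq`, `p`, `beta`, `se`, `b`, `c`.
#' @export
tdt_test <- function(b, c) {
  if (b + c <= 0) stop("b + c must be > 0")
  chisq <- (b - c)^2 / (b + c)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  bb <- b; cc <- c
  if (b == 0 || c == 0) { bb <- b + 0.5; cc <- c + 0.5 }
  list(chisq = chisq, p = p, beta = log(bb / cc),
       se = sqrt(1 / bb + 1 / cc), b = b, c = c)
}

#' TDT scan over all SNPs of a trio set
#'
#' Runs [tdt_counts()] and [tdt_test()] at every SNP and returns a
#' SummaryStats table on the log-odds scale. SNPs with no informative
#' parents are dropped (recorded in the `dropped` attribute).
#'
#' @param trios a `trio_set`.
#' @return SummaryStats data.frame (columns snp_id, chrom, pos,
#'   effect_allele, other_allele, beta, se, p, eaf, n).
#' @export
tdt_scan <- function(trios) {
  info <- trios$snp_info
  rows <- vector("list", nrow(info))
  dropped <- character(0)
  parents <- rbind(trios$father, trios$mother)
  for (i in seq_len(nrow(info))) {
    cnt <- tdt_counts(trios, info$snp_id[i])
    if (cnt$flagged) { dropped <- c(dropped, info$snp_id[i]); next }
    tt <- tdt_test(cnt$b, cnt$c)
    eaf <- mean(parents[, info$snp_id[i]], na.rm = TRUE) / 2
    rows[[i]] <- data.frame(
      snp_id = info$snp_id[i], chrom = info$chrom[i], pos = info$pos[i],
      effect_allele = info$effect_allele[i],
      other_allele = info$other_allele[i],
      beta = tt$beta, se = tt$se, p = tt$p, eaf = eaf,
      n = cnt$n_informative, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Per-SNP logistic case-control association
#'
#' Logistic regression of disease on additive dosage (plus optional
#' covariates); `beta` is the log odds ratio per effect allele with Wald SE
#' and two-sided normal p. Monomorphic SNPs and SNPs with (quasi-)separation
#' are flagged and excluded from the returned table (see the `dropped`
#' attribute).
#'
#' @param panel genotype panel.
#' @param phenotype 0/1 disease vector (at least one case and one control).
#' @param covariates optional covariate table, converted with the same
#'   design rules as the mQTL scan.
#' @param snp_ids optional subset of SNPs to test.
#' @return SummaryStats data.frame; attribute `dropped` is a data.frame of
#'   excluded SNPs with reasons.
#' @export
case_control_assoc <- function(panel, phenotype, covariates = NULL,
                               snp_ids = NULL) {
  y <- as.integer(phenotype)
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("need at least one case and one control")
  }
  info <- panel$snp_info
  if (!is.null(snp_ids)) info <- info[match(snp_ids, info$snp_id), ]
  if (anyNA(panel$dosage[, info$snp_id])) stop("missing dosages not allowed")
  design0 <- covariate_design(covariates)
  rows <- vector("list", nrow(info))
  dropped <- list()
  for (i in seq_len(nrow(info))) {
    g <- panel$dosage[, info$snp_id[i]]
    if (var(g) == 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(snp_id = info$snp_id[i], reason = "monomorphic")
      next
    }
    X <- cbind(`(Intercept)` = 1, dosage = g, design0)
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(), control = list(maxit = 50)))
    cf <- fit$coefficients["dosage"]
    # observed-information Wald SE
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    se <- if (is.null(cov)) Inf else sqrt(cov["dosage", "dosage"])
    if (!is.finite(se) || se > 100 || abs(cf) > 15 || !fit$converged) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(snp_id = info$snp_id[i], reason = "separation")
      next
    }
    rows[[i]] <- data.frame(
      snp_id = info$snp_id[i], chrom = info$chrom[i], pos = info$pos[i],
      effect_allele = info$effect_allele[i],
      other_allele = info$other_allele[i],
      beta = unname(cf), se = unname(se), p = normal_p(cf, se),
      eaf = mean(g) / 2, n = length(y), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- summary_stats(character(0), character(0), integer(0),
                         character(0), character(0), numeric(0),
                         numeric(0), numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                          else data.frame(snp_id = character(0),
                                          reason = character(0))
  out
}

# Allele harmonization between a reference orientation and a second record.
# Returns one of "match", "swap", "flip", "flip_swap", "drop_palindromic",
# "drop_mismatch". Palindromic SNPs (A/T or C/G) are dropped when the
# second study's EAF is missing or in [0.42, 0.58]; otherwise EAF
# concordance decides orientation.
harmonize_alleles <- function(ea_ref, oa_ref, ea, oa,
                              eaf_ref = NA_real_, eaf = NA_real_) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- ea_ref == comp[[oa_ref]]
  if (palindromic) {
    if (!setequal(c(ea, oa), c(ea_ref, oa_ref))) return("drop_mismatch")
    if (is.na(eaf) || is.na(eaf_ref) ||
        (eaf >= 0.42 && eaf <= 0.58) || (eaf_ref >= 0.42 && eaf_ref <= 0.58)) {
      return("drop_palindromic")
    }
    same_side <- (eaf < 0.5) == (eaf_ref < 0.5)
    return(if (same_side) "match" else "swap")
  }
  if (ea == ea_ref && oa == oa_ref) return("match")
  if (ea == oa_ref && oa == ea_ref) return("swap")
  if (comp[[ea]] == ea_ref && comp[[oa]] == oa_ref) return("flip")
  if (comp[[ea]] == oa_ref && comp[[oa]] == ea_ref) return("flip_swap")
  "drop_mismatch"
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-SNP log-odds estimates across studies with weights
#' `1/se^2`: `beta = sum(w_i beta_i) / sum(w_i)`, `se = sqrt(1/sum(w_i))`,
#' p from the two-sided normal. Effect alleles are harmonized to the first
#' study's orientation (sign flips for swapped alleles, strand flips by
#' complement); SNPs whose allele sets cannot be reconciled, and ambiguous
#' palindromic SNPs, are dropped with a logged reason. Only SNPs present in
#' at least two studies are returned.
#'
#' @param studies named list of SummaryStats data.frames.
#' @return SummaryStats data.frame; attribute `dropped` records exclusions.
#' @export
fixed_effect_meta <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 2)
  ref <- studies[[1]]
  dropped <- list()
  all_ids <- unique(unlist(lapply(studies, `[[`, "snp_id")))
  rows <- vector("list", length(all_ids))
  for (k in seq_along(all_ids)) {
    id <- all_ids[k]
    recs <- list()
    refrow <- NULL
    for (s in seq_along(studies)) {
      st <- studies[[s]]
      i <- match(id, st$snp_id)
      if (is.na(i)) next
      row <- st[i, ]
      if (is.null(refrow)) {
        refrow <- row
        recs[[length(recs) + 1L]] <- row
        next
      }
      act <- harmonize_alleles(refrow$effect_allele, refrow$other_allele,
                               row$effect_allele, row$other_allele,
                               refrow$eaf, row$eaf)
      if (act %in% c("drop_palindromic", "drop_mismatch")) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(snp_id = id, study = s, reason = act)
        next
      }
      if (act %in% c("swap", "flip_swap")) {
        row$beta <- -row$beta
        row$eaf <- 1 - row$eaf
      }
      row$effect_allele <- refrow$effect_allele
      row$other_allele <- refrow$other_allele
      recs[[length(recs) + 1L]] <- row
    }
    if (length(recs) < 2) next
    betas <- vapply(recs, `[[`, 0, "beta")
    ses <- vapply(recs, `[[`, 0, "se")
    w <- 1 / ses^2
    beta <- sum(w * betas) / sum(w)
    se <- sqrt(1 / sum(w))
    rows[[k]] <- data.frame(
      snp_id = id, chrom = refrow$chrom, pos = refrow$pos,
      effect_allele = refrow$effect_allele,
      other_allele = refrow$other_allele,
      beta = beta, se = se, p = normal_p(beta, se),
      eaf = refrow$eaf,
      n = sum(vapply(recs, `[[`, 0, "n"), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- summary_stats(character(0), character(0), integer(0),
                         character(0), character(0), numeric(0),
                         numeric(0), numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                          else data.frame(snp_id = character(0),
                                          study = integer(0),
                                          reason = character(0))
  out
}

#' Pairwise LD (signed dosage correlation) matrix
#'
#' Pearson correlation of additive dosages in a reference panel. Monomorphic
#' SNPs have no defined correlation and raise an error naming the SNP.
#'
#' @param panel genotype panel (`>= 2` individuals).
#' @param snp_ids optional subset (order preserved).
#' @return symmetric correlation matrix with unit diagonal and SNP ids as
#'   dimnames.
#' @export
compute_ld <- function(panel, snp_ids = NULL) {
  dosage <- panel$dosage
  if (nrow(dosage) < 2) stop("need >= 2 individuals for LD")
  if (!is.null(snp_ids)) {
    miss <- setdiff(snp_ids, colnames(dosage))
    if (length(miss)) stop("SNP(s) absent from panel: ",
                           paste(miss, collapse = ", "))
    dosage <- dosage[, snp_ids, drop = FALSE]
  }
  v <- apply(dosage, 2, var)
  if (any(v == 0)) stop("monomorphic SNP in LD panel: ",
                        colnames(dosage)[which(v == 0)[1]])
  r <- cor(dosage)
  diag(r) <- 1
  r
}

# Ridge-stabilize a correlation matrix ahead of inversion.
ld_ridge <- function(R, eps = 1e-6) R + diag(eps, nrow(R))

#' Greedy LD clumping of summary statistics
#'
#' Sorts SNPs by ascending p (ties broken by `snp_id`), repeatedly takes the
#' best remaining SNP as an index variant and removes every SNP within
#' `window_kb` of it whose `r^2` with it is at least `r2_threshold`. The
#' returned index SNPs therefore pairwise satisfy distance > window OR
#' r^2 < threshold. SNPs absent from the LD panel are dropped with a
#' warning.
#'
#' @param stats SummaryStats data.frame.
#' @param ld_panel genotype panel used as the LD reference.
#' @param r2_threshold clumping r-squared (default 0.001).
#' @param window_kb window half-width in kb (default 250).
#' @return character vector of index `snp_id`s (in selection order).
#' @export
clump <- function(stats, ld_panel, r2_threshold = 0.001, window_kb = 250) {
  if (nrow(stats) == 0) stop("empty summary statistics")
  present <- stats$snp_id %in% colnames(ld_panel$dosage)
  if (any(!present)) {
    warning("dropping ", sum(!present), " SNP(s) absent from the LD panel: ",
            paste(stats$snp_id[!present], collapse = ", "))
    stats <- stats[present, , drop = FALSE]
  }
  if (nrow(stats) == 0) return(character(0))
  ord <- order(stats$p, stats$snp_id)
  stats <- stats[ord, , drop = FALSE]
  window <- window_kb * 1000
  remaining <- seq_len(nrow(stats))
  index <- character(0)
  dosage <- ld_panel$dosage
  while (length(remaining)) {
    i <- remaining[1]
    index <- c(index, stats$snp_id[i])
    near <- remaining[abs(stats$pos[remaining] - stats$pos[i]) <= window &
                        stats$chrom[remaining] == stats$chrom[i]]
    if (length(near)) {
      r <- suppressWarnings(
        cor(dosage[, stats$snp_id[i]],
            dosage[, stats$snp_id[near], drop = FALSE]))
      kill <- near[!is.na(r) & r^2 >= r2_threshold]
      remaining <- setdiff(remaining, union(kill, i))
    } else {
      remaining <- setdiff(remaining, i)
    }
  }
  index
}
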