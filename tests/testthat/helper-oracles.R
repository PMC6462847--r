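# Independent reference implementations and small fixture builders used
# across the suite. These deliberately avoid the package's own code paths.

# Naive clumping reference: explicit loops, full pairwise LD up front.
clump_reference <- function(stats, panel, r2_threshold, window_kb) {
  stats <- stats[order(stats$p, stats$snp_id), ]
  r <- suppressWarnings(cor(panel$dosage[, stats$snp_id, drop = FALSE]))
  window <- window_kb * 1000
  alive <- rep(TRUE, nrow(stats))
  kept <- character(0)
  repeat {
    i <- which(alive)[1]
    if (is.na(i)) break
    kept <- c(kept, stats$snp_id[i])
    for (j in which(alive)) {
      close_by <- stats$chrom[j] == stats$chrom[i] &&
        abs(stats$pos[j] - stats$pos[i]) <= window
      in_ld <- !is.na(r[i, j]) && r[i, j]^2 >= r2_threshold
      if (j == i || (close_by && in_ld)) alive[j] <- FALSE
    }
  }
  kept
}

# Hand-rolled genotype panel from an explicit dosage matrix.
manual_panel <- function(dosage, pos = NULL, chrom = "1",
                         ea = NULL, oa = NULL) {
  m <- ncol(dosage)
  ids <- colnames(dosage) %||% sprintf("snp_%04d", seq_len(m))
  colnames(dosage) <- ids
  structure(list(
    dosage = dosage,
    snp_info = data.frame(
      snp_id = ids, chrom = chrom,
      pos = as.integer(pos %||% seq(1e5, by = 5e4, length.out = m)),
      effect_allele = ea %||% rep("A", m),
      other_allele = oa %||% rep("G", m),
      maf = colMeans(dosage) / 2, block = seq_len(m),
      stringsAsFactors = FALSE)),
    class = "genotype_panel")
}

# Hand-rolled trio set from explicit parent/child dosage vectors (one SNP).
manual_trios <- function(father, mother, child) {
  f <- matrix(as.integer(father), ncol = 1,
              dimnames = list(NULL, "snp_0001"))
  m <- matrix(as.integer(mother), ncol = 1,
              dimnames = list(NULL, "snp_0001"))
  k <- matrix(as.integer(child), ncol = 1,
              dimnames = list(NULL, "snp_0001"))
  structure(list(father = f, mother = m, child = k,
                 child_affected = rep(TRUE, length(father)),
                 snp_info = data.frame(
                   snp_id = "snp_0001", chrom = "1", pos = 1000L,
                   effect_allele = "A", other_allele = "G", maf = 0.3,
                   block = 1L, stringsAsFactors = FALSE)),
            class = "trio_set")
}

# Summary-stats row builder for harmonization/meta tests.
ss_row <- function(snp_id, beta, se, ea = "A", oa = "G", eaf = 0.3,
                   chrom = "1", pos = 1000L, n = 1000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = ea, other_allele = oa, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), eaf = eaf, n = n,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
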