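# Joint-likelihood colocalization. The model: within a window, each trait's
# vector of association z-scores is multivariate normal with covariance
# equal to the signed LD matrix R, and under a single causal variant at
# index j the mean is lambda * R[, j]. Profiling lambda gives a closed-form
# maximized likelihood per candidate index; the test statistic contrasts
# the best trait-2 likelihood over SNPs in high LD with the trait-1 lead
# ("shared support") against the best over clearly distinct SNPs.
# Significance is by permutation of the trait-2 phenotype residuals.

#' Construct a colocalization window
#'
#' @param snp_ids SNP identifiers, ordered by position.
#' @param z1 trait-1 (disease) z-scores.
#' @param z2 trait-2 (methylation) z-scores.
#' @param R signed LD correlation matrix over the same SNPs.
#' @param r2_resolution genetic-resolution limit: SNPs with `r^2` to the
#'   trait-1 lead at or above this value are treated as indistinguishable
#'   from it (default 0.8).
#' @param buffer SNPs with `r^2` in `[r2_resolution - buffer,
#'   r2_resolution)` are excluded from the distinct support, so
#'   near-threshold SNPs are not penalized (default 0.05).
#' @return object of class `coloc_window`.
#' @export
coloc_window <- function(snp_ids, z1, z2, R, r2_resolution = 0.8,
                         buffer = 0.05) {
  m <- length(snp_ids)
  stopifnot(length(z1) == m, length(z2) == m,
            is.matrix(R), nrow(R) == m, ncol(R) == m)
  if (r2_resolution <= 0 || r2_resolution >= 1) {
    stop("r2_resolution must be in (0, 1)")
  }
  if (max(abs(R - t(R))) > 1e-8) stop("LD matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("LD matrix must have unit diagonal")
  structure(list(snp_ids = snp_ids, z1 = as.numeric(z1),
                 z2 = as.numeric(z2), R = R,
                 r2_resolution = r2_resolution, buffer = buffer),
            class = "coloc_window")
}

#' Profile log-likelihood of a single causal variant at index j
#'
#' Under `z ~ MVN(lambda * R[, j], R)` the non-centrality `lambda` has the
#' closed-form maximizer `(R[,j]' R^-1 z) / (R[,j]' R^-1 R[,j])`; the
#' returned value is the maximized log-density. `R` is ridge-stabilized
#' before inversion.
#'
#' @param z z-score vector.
#' @param R signed LD matrix.
#' @param j candidate causal index.
#' @param ridge diagonal stabilizer (default 1e-6).
#' @return maximized log-likelihood (scalar).
#' @export
single_causal_loglik <- function(z, R, j, ridge = 1e-6) {
  m <- length(z)
  stopifnot(j >= 1, j <= m)
  sigma <- ld_ridge(R, ridge)
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("LD matrix singular even after ridge stabilization")
  })
  si_z <- backsolve(ch, backsolve(ch, z, transpose = TRUE))
  a <- R[, j]
  si_a <- backsolve(ch, backsolve(ch, a, transpose = TRUE))
  lambda <- drop(a %*% si_z) / drop(a %*% si_a)
  resid <- z - lambda * a
  si_r <- backsolve(ch, backsolve(ch, resid, transpose = TRUE))
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * m * log(2 * pi) - 0.5 * logdet - 0.5 * drop(resid %*% si_r)
}

# Precompute the per-window quantities that make the profiled likelihood a
# function of z alone: with Sigma = R + ridge*I, B = Sigma^-1 R and
# d_j = (R' Sigma^-1 R)_jj, the maximized log-likelihood at index j is
# const(z) + 0.5 * (B'z)_j^2 / d_j, where const(z) is common to all j and
# cancels in every support contrast.
coloc_core <- function(R, ridge = 1e-6) {
  sigma <- ld_ridge(R, ridge)
  B <- solve(sigma, R)
  d <- colSums(R * B)
  list(B = B, d = d)
}

# Support contrast for one z2 vector given precomputed core and supports.
support_contrast <- function(core, z2, shared, distinct, agg = "max") {
  u2d <- drop(crossprod(core$B, z2))^2 / core$d
  if (agg == "max") {
    0.5 * (max(u2d[shared]) - max(u2d[distinct]))
  } else {
    # summed (Bayes-like) variant: log-sum-exp of the profiled likelihoods
    lse <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }
    lse(0.5 * u2d[shared]) - lse(0.5 * u2d[distinct])
  }
}

# Shared/distinct support split around the trait-1 lead SNP.
window_supports <- function(window) {
  j1 <- which.max(abs(window$z1))
  r2 <- window$R[, j1]^2
  shared <- which(r2 >= window$r2_resolution)
  distinct <- which(r2 < window$r2_resolution - window$buffer)
  list(lead = j1, shared = shared, distinct = distinct)
}

#' Joint-likelihood colocalization statistic
#'
#' Splits the window at the trait-1 lead SNP (`argmax |z1|`) into a shared
#' support (SNPs with `r^2 >= r2_resolution` to the lead) and a distinct
#' support (`r^2 < r2_resolution - buffer`), and contrasts the best
#' single-causal-variant profile likelihood of the trait-2 z-scores over
#' the two supports. Positive values favor a shared causal variant;
#' strongly negative values indicate the trait-2 signal sits on a variant
#' distinguishable from the trait-1 lead (linkage). When either support is
#' empty (sparsely genotyped window) an undefined-statistic sentinel is
#' returned instead of a value.
#'
#' @param window a [coloc_window()].
#' @param agg `"max"` (default, likelihood-ratio style) or `"sum"`
#'   (summed/Bayes-like sensitivity variant).
#' @param ridge diagonal stabilizer for the LD matrix.
#' @return list with `statistic`, `lead`, `shared`, `distinct`,
#'   `n_snps_shared_support`, `n_snps_distinct_support`, `sentinel`,
#'   `reason`.
#' @export
jlim_statistic <- function(window, agg = c("max", "sum"), ridge = 1e-6) {
  agg <- match.arg(agg)
  sup <- window_supports(window)
  if (!length(sup$shared) || !length(sup$distinct)) {
    return(list(statistic = NA_real_, lead = sup$lead,
                shared = sup$shared, distinct = sup$distinct,
                n_snps_shared_support = length(sup$shared),
                n_snps_distinct_support = length(sup$distinct),
                sentinel = TRUE,
                reason = "window too sparse: empty shared or distinct support"))
  }
  core <- coloc_core(window$R, ridge)
  stat <- support_contrast(core, window$z2, sup$shared, sup$distinct, agg)
  list(statistic = stat, lead = sup$lead, shared = sup$shared,
       distinct = sup$distinct,
       n_snps_shared_support = length(sup$shared),
       n_snps_distinct_support = length(sup$distinct),
       sentinel = FALSE, reason = NA_character_)
}

#' Permutation p-value for the colocalization statistic
#'
#' Requires individual-level trait-2 data (residualized phenotype and
#' genotypes for the window SNPs). Phenotype residuals are permuted across
#' individuals, trait-2 z-scores and the statistic are recomputed for each
#' permutation, and the add-one estimator
#' `p = (1 + #permuted >= observed) / (1 + n_permutations)` is returned.
#' Deterministic given `seed`.
#'
#' @param window a [coloc_window()].
#' @param trait2_genotypes genotype matrix (individuals x window SNPs) or a
#'   `genotype_panel`; columns matched to `window$snp_ids`.
#' @param trait2_residuals residualized trait-2 phenotype vector.
#' @param n_permutations at least 100.
#' @param seed RNG seed.
#' @param agg statistic variant, as in [jlim_statistic()].
#' @param ridge diagonal stabilizer.
#' @return object of class `coloc_result`: `statistic`, `p_permutation`,
#'   `n_permutations`, support sizes, `sentinel`, `reason`.
#' @export
jlim_permutation_p <- function(window, trait2_genotypes, trait2_residuals,
                               n_permutations = 1000, seed = 1,
                               agg = c("max", "sum"), ridge = 1e-6) {
  agg <- match.arg(agg)
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (inherits(trait2_genotypes, "genotype_panel")) {
    trait2_genotypes <- trait2_genotypes$dosage
  }
  if (is.null(trait2_genotypes) || is.null(trait2_residuals)) {
    stop("individual-level trait-2 data (genotypes and residuals) are ",
         "required for the permutation p-value")
  }
  miss <- setdiff(window$snp_ids, colnames(trait2_genotypes))
  if (length(miss)) stop("trait-2 genotypes missing window SNP(s): ",
                         paste(miss, collapse = ", "))
  G <- trait2_genotypes[, window$snp_ids, drop = FALSE]
  y <- as.numeric(trait2_residuals)
  n <- length(y)
  stopifnot(nrow(G) == n)

  obs <- jlim_statistic(window, agg = agg, ridge = ridge)
  if (obs$sentinel) {
    return(structure(c(obs[c("statistic", "n_snps_shared_support",
                             "n_snps_distinct_support", "sentinel",
                             "reason")],
                       list(p_permutation = NA_real_,
                            n_permutations = as.integer(n_permutations))),
                     class = "coloc_result"))
  }
  core <- coloc_core(window$R, ridge)
  sup <- window_supports(window)
  Gs <- scale(G)            # columns standardized
  with_seed(seed, {
    perms <- replicate(n_permutations, sample.int(n))
    Ys <- matrix(scale(y)[perms], n, n_permutations)
    rmat <- crossprod(Gs, Ys) / (n - 1)
    rmat[rmat > 0.999999] <- 0.999999
    rmat[rmat < -0.999999] <- -0.999999
    zmat <- rmat * sqrt((n - 2) / (1 - rmat^2))
    stat_perm <- vapply(seq_len(n_permutations), function(p) {
      support_contrast(core, zmat[, p], sup$shared, sup$distinct, agg)
    }, 0)
    p <- (1 + sum(stat_perm >= obs$statistic)) / (1 + n_permutations)
    structure(list(statistic = obs$statistic, p_permutation = p,
                   n_permutations = as.integer(n_permutations),
                   n_snps_shared_support = obs$n_snps_shared_support,
                   n_snps_distinct_support = obs$n_snps_distinct_support,
                   sentinel = FALSE, reason = NA_character_),
              class = "coloc_result")
  })
}

# Sentinel coloc result (used by the classifier when a window cannot be
# tested, mirroring "too sparsely genotyped" table footnotes).
coloc_sentinel <- function(reason = "window too sparse") {
  structure(list(statistic = NA_real_, p_permutation = NA_real_,
                 n_permutations = 0L, n_snps_shared_support = 0L,
                 n_snps_distinct_support = 0L, sentinel = TRUE,
                 reason = reason),
            class = "coloc_result")
}
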