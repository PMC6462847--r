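# Synthetic cohorts with known causal structure.
#
# The generator follows the study design the analysis pipeline assumes:
# haplotypes with block LD drawn from a latent-Gaussian threshold model,
# additive cis-mQTL effects on a latent (logit-scale) methylation value,
# covariate/batch/cell-composition structure, binary disease through a
# liability-threshold model, and affected-offspring-ascertained trios.
# Five causal models are supported: mediation (G -> M -> D), reverse
# causation (liability -> M), linkage (two correlated variants, one per
# trait), horizontal pleiotropy (one variant, two independent paths), and
# null.

#' Build a haplotype pool with block-exchangeable LD
#'
#' Haplotypes are generated from a latent-Gaussian threshold model: within
#' each LD block, standard-normal latents share an exchangeable correlation
#' `within_block_rho`, and an allele is present when the latent falls below
#' the MAF quantile. Genotype-level LD is therefore controllable but
#' attenuated relative to the latent correlation (tetrachoric-style
#' attenuation); use [latent_rho_for_allele_r()] to hit a target allele
#' correlation exactly.
#'
#' @param n_snps number of SNPs (single chromosome, positions strictly
#'   increasing).
#' @param maf_low,maf_high bounds for target minor-allele frequencies,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param block_sizes integer partition of the SNPs into LD blocks;
#'   must sum to `n_snps`.
#' @param within_block_rho latent correlation in `[0, 1)`, scalar or one
#'   value per block.
#' @param pool_size number of diploid founders; the pool holds
#'   `2 * pool_size` haplotypes. Minimum 100.
#' @param seed RNG seed; the pool is a pure function of its arguments.
#' @param mafs optional explicit per-SNP MAFs (overrides `maf_low`/`maf_high`).
#' @param positions optional strictly increasing base-pair positions.
#' @param chrom chromosome label.
#' @param coupling optional `list(blocks = c(i, j), latent_rho = g)` giving a
#'   shared latent factor between two blocks, so cross-block LD can be
#'   induced (used by the linkage scenario).
#' @return object of class `haplotype_pool`: haplotype matrix
#'   (`2*pool_size` x `n_snps`, 0/1), `snp_info` table (snp_id, chrom, pos,
#'   effect_allele, other_allele, maf, block) and block metadata. The
#'   effect allele is the one whose frequency equals `maf`.
#' @export
make_haplotype_pool <- function(n_snps, maf_low = 0.05, maf_high = 0.5,
                                block_sizes = n_snps, within_block_rho = 0,
                                pool_size = 5000, seed = 1, mafs = NULL,
                                positions = NULL, chrom = "1",
                                coupling = NULL) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("invalid MAF range: need 0 < maf_low <= maf_high <= 0.5")
  }
  if (sum(block_sizes) != n_snps) {
    stop("block_sizes must sum to n_snps (", sum(block_sizes), " != ",
         n_snps, ")")
  }
  if (pool_size < 100) stop("pool_size must be >= 100")
  n_blocks <- length(block_sizes)
  rho <- rep_len(within_block_rho, n_blocks)
  if (any(rho < 0 | rho >= 1)) stop("within_block_rho must be in [0, 1)")
  if (!is.null(positions) && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  block <- rep(seq_len(n_blocks), block_sizes)

  with_seed(seed, {
    if (is.null(mafs)) mafs <- runif(n_snps, maf_low, maf_high)
    if (any(mafs < maf_low - 1e-12 | mafs > maf_high + 1e-12)) {
      stop("explicit mafs outside [maf_low, maf_high]")
    }
    if (is.null(positions)) positions <- cumsum(sample(1000:5000, n_snps, TRUE))

    n_hap <- 2L * as.integer(pool_size)
    # block factors, optionally coupled
    u <- matrix(rnorm(n_hap * n_blocks), n_hap, n_blocks)
    if (!is.null(coupling)) {
      b1 <- coupling$blocks[1]; b2 <- coupling$blocks[2]
      cc <- coupling$latent_rho / sqrt(rho[b1] * rho[b2])
      if (!is.finite(cc) || cc > 1) {
        stop("coupling latent_rho incompatible with within_block_rho")
      }
      u[, b2] <- cc * u[, b1] + sqrt(1 - cc^2) * u[, b2]
    }
    z <- matrix(rnorm(n_hap * n_snps), n_hap, n_snps)
    for (j in seq_len(n_snps)) {
      b <- block[j]
      z[, j] <- sqrt(rho[b]) * u[, b] + sqrt(1 - rho[b]) * z[, j]
    }
    hap <- matrix(0L, n_hap, n_snps)
    hap[z < rep(qnorm(mafs), each = n_hap)] <- 1L

    cf <- colMeans(hap)
    if (any(cf == 0 | cf == 1)) {
      stop("monomorphic haplotype column at SNP index ",
           which(cf == 0 | cf == 1)[1])
    }
    # non-palindromic allele pairs so harmonization never drops simulated SNPs
    pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    al <- pairs[sample.int(4L, n_snps, TRUE)]
    snp_info <- data.frame(
      snp_id = sprintf("snp_%04d", seq_len(n_snps)),
      chrom = chrom,
      pos = as.integer(positions),
      effect_allele = vapply(al, `[`, "", 1L),
      other_allele = vapply(al, `[`, "", 2L),
      maf = mafs,
      block = block,
      stringsAsFactors = FALSE
    )
    colnames(hap) <- snp_info$snp_id
    structure(list(haplotypes = hap, snp_info = snp_info,
                   block_sizes = block_sizes, within_block_rho = rho,
                   pool_size = as.integer(pool_size)),
              class = "haplotype_pool")
  })
}

#' Latent correlation needed for a target allele-dosage correlation
#'
#' Inverts the dichotomized-Gaussian relationship: for haplotype indicators
#' thresholded at the MAF quantiles, the allele (and hence additive dosage)
#' correlation is `(P11 - maf1*maf2) / sqrt(maf1 q1 maf2 q2)` where `P11` is
#' the bivariate-normal orthant probability at latent correlation `rho`.
#'
#' @param target_r desired allele/dosage correlation in `(0, 1)`.
#' @param maf1,maf2 allele frequencies of the two SNPs.
#' @return latent Gaussian correlation achieving `target_r`.
#' @export
latent_rho_for_allele_r <- function(target_r, maf1, maf2) {
  if (target_r <= 0 || target_r >= 1) stop("target_r must be in (0, 1)")
  f <- function(rho) allele_r_from_latent(rho, maf1, maf2) - target_r
  stats::uniroot(f, c(1e-8, 1 - 1e-8), tol = 1e-10)$root
}

allele_r_from_latent <- function(rho, maf1, maf2) {
  p11 <- mvtnorm::pmvnorm(upper = c(qnorm(maf1), qnorm(maf2)),
                          corr = matrix(c(1, rho, rho, 1), 2))
  (as.numeric(p11) - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Draw diploid genotypes from a haplotype pool
#'
#' Each individual is the sum of two haplotypes sampled uniformly with
#' replacement, so genotype frequencies follow Hardy-Weinberg proportions at
#' the pool allele frequencies.
#'
#' @param pool a [make_haplotype_pool()] object.
#' @param n_individuals number of individuals (`>= 1`).
#' @param seed RNG seed.
#' @return object of class `genotype_panel`: integer `dosage` matrix
#'   (individuals x SNPs, values 0/1/2, SNP ids as column names) plus the
#'   pool's `snp_info`. Doubles as an LD reference panel.
#' @export
draw_genotypes <- function(pool, n_individuals, seed = 1) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  n_hap <- nrow(pool$haplotypes)
  if (n_hap == 0) stop("empty haplotype pool")
  with_seed(seed, {
    i1 <- sample.int(n_hap, n_individuals, replace = TRUE)
    i2 <- sample.int(n_hap, n_individuals, replace = TRUE)
    dosage <- pool$haplotypes[i1, , drop = FALSE] +
      pool$haplotypes[i2, , drop = FALSE]
    rownames(dosage) <- sprintf("ind_%05d", seq_len(n_individuals))
    structure(list(dosage = dosage, snp_info = pool$snp_info),
              class = "genotype_panel")
  })
}

#' Simulate the covariate table the mQTL recipe adjusts for
#'
#' Sex, ancestry principal components, a bisulfite-conversion batch label and
#' blood cell-type proportions (Dirichlet-distributed, summing to one), the
#' covariates the cis-mQTL scan residualizes on.
#'
#' @param n number of individuals.
#' @param n_pcs number of ancestry PCs (default 10).
#' @param n_batches number of batch levels.
#' @param cell_shapes named Dirichlet shape parameters for the cell types;
#'   the defaults mimic whole-blood composition (granulocyte-dominated).
#' @param seed RNG seed.
#' @return data.frame with columns `sex` (0/1), `pc1..pcK`, `batch` (factor)
#'   and `cell_*` proportions.
#' @export
make_covariates <- function(n, n_pcs = 10, n_batches = 3,
                            cell_shapes = c(cell_Bcell = 2, cell_CD4T = 6,
                                            cell_CD8T = 3, cell_Gran = 12,
                                            cell_Mono = 2, cell_NK = 2),
                            seed = 1) {
  with_seed(seed, {
    out <- data.frame(sex = rbinom(n, 1, 0.5))
    for (k in seq_len(n_pcs)) out[[paste0("pc", k)]] <- rnorm(n)
    out$batch <- factor(sample(paste0("batch", seq_len(n_batches)), n, TRUE))
    g <- vapply(cell_shapes, function(a) rgamma(n, shape = a), numeric(n))
    g <- g / rowSums(g)
    for (j in seq_along(cell_shapes)) out[[names(cell_shapes)[j]]] <- g[, j]
    rownames(out) <- sprintf("ind_%05d", seq_len(n))
    out
  })
}

# Numeric design matrix from a covariate table: sex and PCs as-is, batch as
# treatment-coded dummies (first level dropped), cell proportions with the
# first column dropped (compositional: they sum to one).
covariate_design <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  stopifnot(is.data.frame(covariates))
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (nm == "batch" || is.factor(v) || is.character(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, levels(f)[-1])
        cols[[nm]] <- mm
      }
    } else {
      cols[[nm]] <- matrix(as.numeric(v), ncol = 1,
                           dimnames = list(NULL, nm))
    }
  }
  cell_idx <- grep("^cell_", names(cols))
  if (length(cell_idx) > 1) cols[[cell_idx[1]]] <- NULL
  do.call(cbind, unname(cols))
}

#' Simulate methylation beta-values with a single cis-mQTL effect
#'
#' Latent methylation is `intercept + mqtl_effect * dosage + covariate terms
#' + Normal(0, noise_sd)`; beta-values are the logistic transform of the
#' latent, which keeps them in `[0, 1]` and makes the rank-based
#' inverse-normal transform used by the scan exactly appropriate (the latent
#' is normal and the logistic map is monotone). Non-causal CpGs are generated
#' with `mqtl_effect = 0` but share the covariate structure.
#'
#' @param panel a [draw_genotypes()] panel.
#' @param causal_snp_index column index of the causal SNP.
#' @param mqtl_effect latent-scale change per effect allele.
#' @param covariates optional covariate table ([make_covariates()]).
#' @param covariate_effect_sizes effect per design column (scalar recycled).
#' @param noise_sd residual SD of the latent (> 0).
#' @param n_cpgs number of CpGs; only `causal_cpg_index` carries the effect.
#' @param causal_cpg_index which CpG is causal (default 1).
#' @param cpg_info optional data.frame (cpg_id, chrom, pos); by default the
#'   causal CpG sits at the causal SNP's position and the rest at 10 kb
#'   spacings.
#' @param intercept latent intercept (default -1, i.e. mean beta-value ~0.27).
#' @param seed RNG seed.
#' @return list with `beta` (n x n_cpgs matrix in `[0,1]`), `latent`,
#'   `cpg_info` and the covariate table used.
#' @export
simulate_methylation <- function(panel, causal_snp_index, mqtl_effect,
                                 covariates = NULL,
                                 covariate_effect_sizes = 0,
                                 noise_sd = 1, n_cpgs = 1,
                                 causal_cpg_index = 1, cpg_info = NULL,
                                 intercept = -1, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosage)
  if (causal_snp_index < 1 || causal_snp_index > ncol(panel$dosage)) {
    stop("causal_snp_index out of range")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  design <- covariate_design(covariates)
  cov_term <- 0
  if (!is.null(design)) {
    eff <- rep_len(covariate_effect_sizes, ncol(design))
    cov_term <- drop(design %*% eff)
  }
  g <- panel$dosage[, causal_snp_index]
  with_seed(seed, {
    latent <- matrix(rnorm(n * n_cpgs, sd = noise_sd), n, n_cpgs)
    latent <- latent + intercept + cov_term
    latent[, causal_cpg_index] <- latent[, causal_cpg_index] + mqtl_effect * g
    if (is.null(cpg_info)) {
      pos0 <- panel$snp_info$pos[causal_snp_index]
      pos <- pos0 + (seq_len(n_cpgs) - causal_cpg_index) * 10000L
      cpg_info <- data.frame(
        cpg_id = sprintf("cg%08d", seq_len(n_cpgs)),
        chrom = panel$snp_info$chrom[causal_snp_index],
        pos = as.integer(pos), stringsAsFactors = FALSE)
    }
    colnames(latent) <- cpg_info$cpg_id
    beta <- stats::plogis(latent)
    list(beta = beta, latent = latent, cpg_info = cpg_info,
         covariates = covariates, intercept = intercept)
  })
}

#' Scenario configuration for the four causal models
#'
#' Defines the generative model for one locus plus a polygenic disease
#' background. Exactly the focal-path parameters consistent with `model` may
#' be non-zero:
#' \describe{
#'   \item{mediation}{`mqtl_effect`, `methylation_to_liability` (G -> M -> D)}
#'   \item{reverse_causation}{`liability_to_methylation` (liability -> M)}
#'   \item{linkage}{`mqtl_effect`, `direct_snp_to_liability`, `linkage_r2`
#'     (G1 -> M, G2 -> D, corr(G1, G2) set by `linkage_r2`)}
#'   \item{pleiotropy}{`mqtl_effect`, `direct_snp_to_liability` (one SNP,
#'     two independent paths)}
#'   \item{null}{`mqtl_effect` only (an mQTL with no disease involvement)}
#' }
#' The polygenic background (`n_disease_snps` SNPs each adding
#' `disease_snp_liability` liability units per allele) exists in every
#' non-null model: it supplies the independent genome-wide-significant
#' disease instruments that the reverse-MR step requires, and it is the sole
#' source of genetic liability under reverse causation. Under `null` it
#' defaults to zero so that association tests are exactly null.
#'
#' @param model one of `"mediation"`, `"reverse_causation"`, `"linkage"`,
#'   `"pleiotropy"`, `"null"`.
#' @param n_individuals cohort size.
#' @param n_trios number of affected-offspring trios.
#' @param mqtl_effect latent methylation change per effect allele.
#' @param methylation_to_liability liability SD per SD methylation.
#' @param direct_snp_to_liability liability units per allele for the direct
#'   (pleiotropy/linkage) path.
#' @param liability_to_methylation SD methylation per SD genetic liability
#'   (reverse model).
#' @param prevalence population disease probability in (0, 1).
#' @param linkage_r2 target r-squared between the mQTL SNP and the disease
#'   SNP under linkage.
#' @param covariate_effect_sizes per-design-column effect on methylation.
#' @param noise_sd residual SD of latent methylation.
#' @param n_disease_snps,disease_snp_liability polygenic background.
#' @param pool_size haplotype pool founders.
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param pool_seed seed for the haplotype pool (MAFs, positions, alleles,
#'   LD); defaults to `seed`. Two configs sharing `pool_seed` (and model)
#'   describe cohorts drawn from the same population — required for
#'   two-sample analyses, where exposure and outcome cohorts must share
#'   the SNP map.
#' @return validated object of class `scenario_config`.
#' @export
scenario_config <- function(model = c("mediation", "reverse_causation",
                                      "linkage", "pleiotropy", "null"),
                            n_individuals = 2000, n_trios = 300,
                            mqtl_effect = NULL,
                            methylation_to_liability = NULL,
                            direct_snp_to_liability = NULL,
                            liability_to_methylation = NULL,
                            prevalence = 0.1, linkage_r2 = NULL,
                            covariate_effect_sizes = 0.1, noise_sd = 1,
                            n_disease_snps = 6,
                            disease_snp_liability = NULL,
                            pool_size = 5000, seed = 1, pool_seed = NULL) {
  model <- match.arg(model)
  active <- switch(model,
    mediation = c("mqtl_effect", "methylation_to_liability"),
    reverse_causation = "liability_to_methylation",
    linkage = c("mqtl_effect", "direct_snp_to_liability", "linkage_r2"),
    pleiotropy = c("mqtl_effect", "direct_snp_to_liability"),
    null = "mqtl_effect")
  defaults <- list(mqtl_effect = 0.7, methylation_to_liability = 0.7,
                   direct_snp_to_liability = 0.7,
                   liability_to_methylation = 0.7, linkage_r2 = 0.5)
  if (is.null(pool_seed)) pool_seed <- seed
  supplied <- list(mqtl_effect = mqtl_effect,
                   methylation_to_liability = methylation_to_liability,
                   direct_snp_to_liability = direct_snp_to_liability,
                   liability_to_methylation = liability_to_methylation,
                   linkage_r2 = linkage_r2)
  vals <- list()
  for (nm in names(defaults)) {
    if (nm %in% active) {
      vals[[nm]] <- supplied[[nm]] %||% defaults[[nm]]
    } else {
      if (!is.null(supplied[[nm]]) && supplied[[nm]] != 0) {
        stop("parameter `", nm, "` must be zero (or unset) under model `",
             model, "`")
      }
      vals[[nm]] <- 0
    }
  }
  if (is.null(disease_snp_liability)) {
    disease_snp_liability <- if (model == "null") 0 else 0.4
  }
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must be in (0,1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (vals$linkage_r2 < 0 || vals$linkage_r2 >= 1) {
    stop("linkage_r2 must be in [0, 1)")
  }
  structure(c(list(model = model, n_individuals = n_individuals,
                   n_trios = n_trios), vals,
              list(prevalence = prevalence,
                   covariate_effect_sizes = covariate_effect_sizes,
                   noise_sd = noise_sd, n_disease_snps = n_disease_snps,
                   disease_snp_liability = disease_snp_liability,
                   pool_size = pool_size, seed = seed,
                   pool_seed = pool_seed)),
            class = "scenario_config")
}

# Theoretical variance of the scenario's liability predictor, used to place
# the disease threshold so realized prevalence matches the target under
# every model (the liability residual is standard normal; the total SD is
# sqrt(1 + var_predictor)).
predictor_variance <- function(scenario, maf_causal, maf_linked, mafs_bg) {
  v_bg <- sum(scenario$disease_snp_liability^2 * 2 * mafs_bg * (1 - mafs_bg))
  v <- v_bg
  v <- v + switch(scenario$model,
    mediation = scenario$methylation_to_liability^2,
    pleiotropy = scenario$direct_snp_to_liability^2 *
      2 * maf_causal * (1 - maf_causal),
    linkage = scenario$direct_snp_to_liability^2 *
      2 * maf_linked * (1 - maf_linked),
    reverse_causation = 0,
    null = 0)
  v
}

#' Simulate disease status under a scenario's liability-threshold model
#'
#' Liability is the scenario-specific linear predictor plus standard-normal
#' noise; disease occurs above the `1 - prevalence` quantile of the
#' theoretical liability distribution (threshold scaled by the total
#' liability SD so realized prevalence matches the target in every model).
#' Under reverse causation the latent methylation is regenerated as
#' `liability_to_methylation * standardized genetic liability + noise` and
#' returned.
#'
#' @param panel genotype panel.
#' @param methylation_latent_std standardized latent methylation of the focal
#'   CpG (used by the mediation path).
#' @param scenario a [scenario_config()].
#' @param causal_snp_index,linked_snp_index,disease_snp_index column indices
#'   of the focal mQTL SNP, the linkage-partner SNP, and the polygenic
#'   background SNPs.
#' @param seed RNG seed.
#' @return list: `phenotype` (0/1), `liability`, `threshold`, and
#'   `methylation_latent` (non-NULL only under reverse causation).
#' @export
simulate_disease <- function(panel, methylation_latent_std, scenario,
                             causal_snp_index, linked_snp_index = NULL,
                             disease_snp_index = integer(0), seed = 1) {
  stopifnot(inherits(scenario, "scenario_config"))
  dosage <- panel$dosage
  n <- nrow(dosage)
  info <- panel$snp_info
  w <- scenario$disease_snp_liability
  mafs_bg <- if (length(disease_snp_index)) info$maf[disease_snp_index]
             else numeric(0)
  # every genetic component is centered at its theoretical mean so the
  # liability has mean zero and the threshold sets the target prevalence
  pgs <- if (length(disease_snp_index) && w != 0) {
    w * (rowSums(dosage[, disease_snp_index, drop = FALSE]) -
           sum(2 * mafs_bg))
  } else rep(0, n)
  if (scenario$model == "reverse_causation" &&
      (!length(disease_snp_index) || w == 0)) {
    stop("reverse_causation requires a non-zero polygenic disease background")
  }
  pred <- pgs + switch(scenario$model,
    mediation = scenario$methylation_to_liability * methylation_latent_std,
    pleiotropy = scenario$direct_snp_to_liability *
      (dosage[, causal_snp_index] - 2 * info$maf[causal_snp_index]),
    linkage = {
      if (is.null(linked_snp_index)) stop("linkage model needs linked_snp_index")
      scenario$direct_snp_to_liability *
        (dosage[, linked_snp_index] - 2 * info$maf[linked_snp_index])
    },
    reverse_causation = 0,
    null = 0)
  v_pred <- predictor_variance(
    scenario, info$maf[causal_snp_index],
    if (!is.null(linked_snp_index)) info$maf[linked_snp_index] else NA_real_,
    mafs_bg)
  threshold <- qnorm(1 - scenario$prevalence) * sqrt(1 + v_pred)
  with_seed(seed, {
    liability <- pred + rnorm(n)
    phenotype <- as.integer(liability > threshold)
    meth_new <- NULL
    if (scenario$model == "reverse_causation") {
      v_bg <- sum(w^2 * 2 * mafs_bg * (1 - mafs_bg))
      gen_liab_std <- (pgs - mean(pgs)) / sqrt(v_bg)
      meth_new <- scenario$liability_to_methylation * gen_liab_std +
        rnorm(n, sd = scenario$noise_sd)
    }
    list(phenotype = phenotype, liability = liability, threshold = threshold,
         methylation_latent = meth_new)
  })
}

#' Simulate affected-offspring-ascertained trios
#'
#' Parents are drawn from the haplotype pool as in [draw_genotypes()]; each
#' parent transmits one haplotype chosen at random; the child's disease
#' status is simulated under the scenario, and families are resampled until
#' `n_trios` affected children are collected (rejection sampling, capped at
#' `max_families` candidate families). Duos are represented as trios with the
#' father's genotypes masked (`NA`).
#'
#' @param pool haplotype pool.
#' @param scenario a [scenario_config()].
#' @param n_trios number of affected-offspring families.
#' @param causal_snp_index,linked_snp_index,disease_snp_index as in
#'   [simulate_disease()].
#' @param n_duos how many families to mask down to mother-child duos.
#' @param max_families rejection-sampling cap.
#' @param seed RNG seed.
#' @return object of class `trio_set`: `father`, `mother`, `child` dosage
#'   matrices over the shared SNP index (masked parents are `NA` rows),
#'   `child_affected` (all `TRUE`), and `snp_info`.
#' @export
simulate_trios <- function(pool, scenario, n_trios,
                           causal_snp_index, linked_snp_index = NULL,
                           disease_snp_index = integer(0),
                           n_duos = 0, max_families = 1e6, seed = 1) {
  stopifnot(inherits(pool, "haplotype_pool"),
            inherits(scenario, "scenario_config"))
  if (n_trios < 1) stop("n_trios must be >= 1")
  hap <- pool$haplotypes
  n_hap <- nrow(hap)
  info <- pool$snp_info
  w <- scenario$disease_snp_liability
  mafs_bg <- if (length(disease_snp_index)) info$maf[disease_snp_index]
             else numeric(0)
  maf_c <- info$maf[causal_snp_index]
  sd_m_child <- sqrt(scenario$mqtl_effect^2 * 2 * maf_c * (1 - maf_c) +
                     scenario$noise_sd^2)
  v_pred <- predictor_variance(
    scenario, maf_c,
    if (!is.null(linked_snp_index)) info$maf[linked_snp_index] else NA_real_,
    mafs_bg)
  threshold <- qnorm(1 - scenario$prevalence) * sqrt(1 + v_pred)

  with_seed(seed, {
    fa <- mo <- ch <- vector("list", 0L)
    got <- 0L
    tried <- 0
    while (got < n_trios) {
      nb <- min(max(1000L, ceiling((n_trios - got) / scenario$prevalence)),
                max_families - tried)
      if (nb <= 0) {
        stop("ascertainment cap reached: examined ", tried,
             " families but collected only ", got, " affected children; ",
             "prevalence may be too low for max_families")
      }
      tried <- tried + nb
      f1 <- sample.int(n_hap, nb, TRUE); f2 <- sample.int(n_hap, nb, TRUE)
      m1 <- sample.int(n_hap, nb, TRUE); m2 <- sample.int(n_hap, nb, TRUE)
      tf <- runif(nb) < 0.5   # which paternal haplotype is transmitted
      tm <- runif(nb) < 0.5
      cf <- ifelse(tf, f1, f2)
      cm <- ifelse(tm, m1, m2)
      child <- hap[cf, , drop = FALSE] + hap[cm, , drop = FALSE]
      pgs <- if (length(disease_snp_index) && w != 0) {
        w * (rowSums(child[, disease_snp_index, drop = FALSE]) -
               sum(2 * mafs_bg))
      } else rep(0, nb)
      pred <- pgs + switch(scenario$model,
        mediation = {
          m_lat <- scenario$mqtl_effect * child[, causal_snp_index] +
            rnorm(nb, sd = scenario$noise_sd)
          scenario$methylation_to_liability *
            (m_lat - scenario$mqtl_effect * 2 * maf_c) / sd_m_child
        },
        pleiotropy = scenario$direct_snp_to_liability *
          (child[, causal_snp_index] - 2 * maf_c),
        linkage = scenario$direct_snp_to_liability *
          (child[, linked_snp_index] -
             2 * info$maf[linked_snp_index]),
        reverse_causation = 0,
        null = 0)
      affected <- (pred + rnorm(nb)) > threshold
      keep <- which(affected)
      if (length(keep)) {
        keep <- keep[seq_len(min(length(keep), n_trios - got))]
        fa[[length(fa) + 1L]] <- hap[f1[keep], , drop = FALSE] +
          hap[f2[keep], , drop = FALSE]
        mo[[length(mo) + 1L]] <- hap[m1[keep], , drop = FALSE] +
          hap[m2[keep], , drop = FALSE]
        ch[[length(ch) + 1L]] <- child[keep, , drop = FALSE]
        got <- got + length(keep)
      }
    }
    father <- do.call(rbind, fa); mother <- do.call(rbind, mo)
    child <- do.call(rbind, ch)
    rownames(father) <- rownames(mother) <- rownames(child) <-
      sprintf("fam_%05d", seq_len(n_trios))
    if (n_duos > 0) father[seq_len(min(n_duos, n_trios)), ] <- NA_integer_
    structure(list(father = father, mother = mother, child = child,
                   child_affected = rep(TRUE, n_trios), snp_info = info),
              class = "trio_set")
  })
}

#' Generate a complete study under one causal scenario
#'
#' One-call factory composing the pool, cohort genotypes, covariates,
#' methylation, disease and trios under a fixed genome layout: a 21-SNP
#' focal LD block (latent rho 0.995, i.e. typical within-block genotype
#' r-squared around 0.85, above the colocalization resolution limit; the
#' middle SNP is the causal mQTL, the focal CpG sits at its position), a
#' 5-SNP secondary block 60 kb away
#' (coupled to the focal block only under linkage, to hit `linkage_r2`), and
#' `n_disease_snps` independent background SNPs 0.3-0.8 Mb away (cis to the
#' CpG, so the reverse-causation signal is discoverable by the scan). All
#' stage seeds derive from `config$seed`, so two calls with the same config
#' are bit-identical.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario_data`: `bundle` (genotype panel,
#'   methylation beta and latent matrices, covariates, phenotype, cpg_info,
#'   `truth` = the config), `trios`, `truth_table` (per-SNP roles and causal
#'   flags), `indices` (causal/linked/background SNP columns) and `seeds`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  n_bg <- config$n_disease_snps
  n_snps <- 21L + 5L + n_bg
  block_sizes <- c(21L, 5L, rep(1L, n_bg))
  rho <- c(0.995, 0.995, rep(0, n_bg))
  positions <- c(seq(950000L, 1050000L, by = 5000L),      # focal block
                 seq(1060000L, 1068000L, by = 2000L),     # secondary block
                 if (n_bg > 0) seq(1300000L, 1300000L + (n_bg - 1) * 100000L,
                                   by = 100000L))
  causal_idx <- 11L
  linked_idx <- 24L
  bg_idx <- if (n_bg > 0) 26L + seq_len(n_bg) else integer(0)

  # LD blocks share a base allele frequency (with small jitter): high
  # within-block genotype r^2 is only attainable when frequencies match
  mafs <- with_seed(config$pool_seed, {
    base_focal <- runif(1, 0.22, 0.38)
    # the secondary block shares the focal base frequency: cross-block LD
    # between dichotomized variants is only attainable when the allele
    # frequencies are close
    base_linked <- base_focal + runif(1, -0.01, 0.01)
    pmin(pmax(c(base_focal + runif(21, -0.01, 0.01),
                base_linked + runif(5, -0.01, 0.01),
                runif(n_bg, 0.2, 0.4)), 0.2), 0.4)
  })
  coupling <- NULL
  if (config$model == "linkage" && config$linkage_r2 > 0) {
    target_r <- sqrt(config$linkage_r2)
    lat <- latent_rho_for_allele_r(target_r, mafs[causal_idx],
                                   mafs[linked_idx])
    coupling <- list(blocks = c(1L, 2L), latent_rho = lat)
  }
  pool <- make_haplotype_pool(
    n_snps, maf_low = 0.2, maf_high = 0.4, block_sizes = block_sizes,
    within_block_rho = rho, pool_size = config$pool_size,
    seed = config$pool_seed + 1,
    mafs = mafs, positions = positions, coupling = coupling)

  panel <- draw_genotypes(pool, config$n_individuals, seed = seed + 2)
  covariates <- make_covariates(config$n_individuals, seed = seed + 3)
  meth <- simulate_methylation(
    panel, causal_snp_index = causal_idx, mqtl_effect = config$mqtl_effect,
    covariates = covariates,
    covariate_effect_sizes = config$covariate_effect_sizes,
    noise_sd = config$noise_sd, seed = seed + 4)
  m_lat <- meth$latent[, 1]
  m_std <- (m_lat - mean(m_lat)) / sd(m_lat)
  dis <- simulate_disease(
    panel, m_std, config, causal_snp_index = causal_idx,
    linked_snp_index = linked_idx, disease_snp_index = bg_idx,
    seed = seed + 5)
  if (!is.null(dis$methylation_latent)) {
    meth$latent[, 1] <- dis$methylation_latent + meth$intercept
    meth$beta[, 1] <- stats::plogis(meth$latent[, 1])
  }
  trios <- if (config$n_trios > 0) {
    simulate_trios(
      pool, config, config$n_trios, causal_snp_index = causal_idx,
      linked_snp_index = linked_idx, disease_snp_index = bg_idx,
      seed = seed + 6)
  } else NULL

  role <- rep("none", n_snps)
  role[causal_idx] <- "mqtl"
  role[linked_idx] <- if (config$model == "linkage") "disease_linked" else "none"
  role[bg_idx] <- "background_disease"
  causal_meth <- seq_len(n_snps) == causal_idx &
    config$model != "reverse_causation" & config$mqtl_effect != 0
  causal_dis <- rep(FALSE, n_snps)
  if (config$model == "mediation") causal_dis[causal_idx] <- TRUE
  if (config$model == "pleiotropy") causal_dis[causal_idx] <- TRUE
  if (config$model == "linkage") causal_dis[linked_idx] <- TRUE
  if (config$disease_snp_liability != 0) causal_dis[bg_idx] <- TRUE
  truth_table <- data.frame(pool$snp_info[, c("snp_id", "chrom", "pos")],
                            role = role,
                            causal_for_methylation = causal_meth,
                            causal_for_disease = causal_dis,
                            stringsAsFactors = FALSE)

  bundle <- list(genotypes = panel, methylation = meth$beta,
                 methylation_latent = meth$latent, covariates = covariates,
                 phenotype = dis$phenotype, cpg_info = meth$cpg_info,
                 truth = config)
  structure(list(bundle = bundle, trios = trios, truth_table = truth_table,
                 pool = pool,
                 indices = list(causal_snp = causal_idx,
                                linked_snp = linked_idx,
                                disease_snps = bg_idx, cpg = 1L),
                 seeds = seed + 0:6),
            class = "scenario_data")
}
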