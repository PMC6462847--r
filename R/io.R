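# Plain-text readers/writers, pipeline configuration, and structured
# logging. All genomic coordinates are 1-based inclusive, matching GWAS
# summary-statistic convention; all files are TSV or JSON.

#' Write summary statistics to TSV
#'
#' Columns in the canonical order: snp_id, chrom, pos, effect_allele,
#' other_allele, beta, se, p, eaf, n.
#'
#' @param stats SummaryStats data.frame.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  validate_summary_stats(stats)
  write.table(stats[, SUMMARY_STATS_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and validate summary statistics from TSV
#'
#' Columns are matched by name, so header order is free. Malformed rows
#' raise errors naming the line and column; rows with `se <= 0` are
#' rejected with a logged warning; `p = 0` (a truncation some tools emit)
#' is clamped to the smallest positive double with a warning.
#'
#' @param path TSV with the canonical summary-statistic columns.
#' @return SummaryStats data.frame.
#' @export
read_summary_stats <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(SUMMARY_STATS_COLS, names(x))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  x <- x[, SUMMARY_STATS_COLS]
  for (col in c("pos", "beta", "se", "p", "eaf", "n")) {
    v <- x[[col]]
    bad <- which(!is.na(v) & !is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad)) stop("malformed value at line ", bad[1] + 1L,
                          " column `", col, "` in ", path)
    x[[col]] <- as.numeric(v)
  }
  x$pos <- as.integer(x$pos)
  zero_p <- !is.na(x$p) & x$p == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " row(s) with p = 0 clamped to the smallest ",
            "positive double")
    x$p[zero_p] <- .Machine$double.xmin
  }
  bad_se <- !is.na(x$se) & x$se <= 0
  if (any(bad_se)) {
    warning("rejecting ", sum(bad_se), " row(s) with se <= 0")
    x <- x[!bad_se, , drop = FALSE]
  }
  rownames(x) <- NULL
  validate_summary_stats(x)
  x
}

#' Write a genotype panel (dosage TSV + SNP map sidecar)
#'
#' Produces `<prefix>_dosages.tsv` (rows = individuals, columns = SNP ids)
#' and `<prefix>_snps.tsv` (snp_id, chrom, pos, effect_allele,
#' other_allele, maf).
#'
#' @param panel genotype panel.
#' @param prefix output path prefix.
#' @export
write_genotype_panel <- function(panel, prefix) {
  d <- data.frame(individual = rownames(panel$dosage) %||%
                    sprintf("ind_%05d", seq_len(nrow(panel$dosage))),
                  panel$dosage, check.names = FALSE)
  write.table(d, paste0(prefix, "_dosages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(panel$snp_info, paste0(prefix, "_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a genotype panel written by [write_genotype_panel()]
#'
#' Dosages must lie in `[0, 2]`; missing or out-of-range entries are
#' rejected naming the offending cell (no imputation is attempted). The
#' SNP-map sidecar is required.
#'
#' @param prefix path prefix used at write time.
#' @return genotype panel.
#' @export
read_genotype_panel <- function(prefix) {
  dos_path <- paste0(prefix, "_dosages.tsv")
  map_path <- paste0(prefix, "_snps.tsv")
  if (!file.exists(map_path)) stop("missing SNP map sidecar: ", map_path)
  if (!file.exists(dos_path)) stop("missing dosage file: ", dos_path)
  d <- read.delim(dos_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty genotype panel in ", dos_path)
  ind <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  bad <- which(is.na(m) | m < 0 | m > 2, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid dosage at individual ", ind[bad[1, 1]], ", SNP ",
         colnames(m)[bad[1, 2]], " (value ",
         m[bad[1, 1], bad[1, 2]], ")")
  }
  rownames(m) <- ind
  info <- read.delim(map_path, stringsAsFactors = FALSE,
                     colClasses = c(chrom = "character"))
  if (!all(colnames(m) == info$snp_id)) {
    stop("dosage columns do not match SNP map order")
  }
  structure(list(dosage = m, snp_info = info), class = "genotype_panel")
}

#' Write a cohort bundle to a directory
#'
#' Genotypes (dosage TSV plus SNP map), methylation, covariates and
#' phenotype TSVs, and the scenario truth as JSON.
#'
#' @param scenario_data a [generate_scenario()] object.
#' @param dir output directory (created if needed).
#' @export
write_cohort_bundle <- function(scenario_data, dir) {
  b <- scenario_data$bundle
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_panel(b$genotypes, file.path(dir, "genotypes"))
  meth <- data.frame(individual = rownames(b$genotypes$dosage),
                     b$methylation, check.names = FALSE)
  write.table(meth, file.path(dir, "methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cov <- data.frame(individual = rownames(b$genotypes$dosage),
                    b$covariates, check.names = FALSE)
  write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  phe <- data.frame(individual = rownames(b$genotypes$dosage),
                    phenotype = b$phenotype)
  write.table(phe, file.path(dir, "phenotype.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(b$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

PIPELINE_CONFIG_DEFAULTS <- list(
  clump_r2 = 0.001, clump_window_kb = 250,
  cis_window_bp = 1e6, mqtl_p_threshold = 1e-7,
  r2_resolution = 0.8, alpha = 0.05,
  n_permutations = 1000, seed = 1,
  coloc_window_bp = 1e5,
  reverse_p_threshold = 0.05, coloc_p_threshold = 0.05)

#' Pipeline configuration
#'
#' Central place for every stage threshold: clumping r-squared (0.001)
#' within a 250 kb window, the 1 Mb cis window and the 1e-7 mQTL threshold,
#' the colocalization r-squared resolution limit of 0.8 and its window,
#' the Bonferroni family-wise alpha, permutations and seed. Unknown keys
#' and out-of-domain values are rejected.
#'
#' @param ... overrides of the defaults.
#' @return validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_CONFIG_DEFAULTS))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_CONFIG_DEFAULTS, over)
  with(cfg, {
    stopifnot(clump_r2 > 0, clump_r2 <= 1, clump_window_kb > 0,
              cis_window_bp > 0, mqtl_p_threshold > 0, mqtl_p_threshold <= 1,
              r2_resolution > 0, r2_resolution < 1,
              alpha > 0, alpha < 1, n_permutations >= 100,
              coloc_window_bp > 0,
              reverse_p_threshold > 0, reverse_p_threshold <= 1,
              coloc_p_threshold > 0, coloc_p_threshold <= 1)
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are a subset of the
#'   [pipeline_config()] keys; unknown keys are rejected.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Structured JSON-lines run logger
#'
#' Every stage can log inputs, parameters, seeds and record counts in/out
#' with drop reasons, in machine-readable form. Entries are accumulated in
#' memory and optionally appended to a file as JSON lines. Timestamps are
#' attached at write time only, so two identical runs produce identical
#' entry lists.
#'
#' @param path optional JSON-lines file to append to.
#' @return object of class `run_logger` with functions `log(stage, event,
#'   ...)`, `entries()` and `counts(stage)`.
#' @export
run_logger <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  log <- function(stage, event, ...) {
    entry <- c(list(stage = stage, event = event), list(...))
    env$entries[[length(env$entries) + 1L]] <- entry
    if (!is.null(path)) {
      line <- jsonlite::toJSON(c(entry, list(time = format(Sys.time()))),
                               auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = path, append = TRUE)
    }
    invisible(entry)
  }
  entries <- function() env$entries
  counts <- function(stage) {
    e <- Filter(function(x) x$stage == stage, env$entries)
    list(n_in = sum(vapply(e, function(x) x$n_in %||% 0, 0)),
         n_out = sum(vapply(e, function(x) x$n_out %||% 0, 0)),
         n_dropped = sum(vapply(e, function(x) x$n_dropped %||% 0, 0)))
  }
  structure(list(log = log, entries = entries, counts = counts),
            class = "run_logger")
}
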