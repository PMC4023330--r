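# End-to-end orchestration: simulate (or load) inputs, phenotype, bulk,
# filter candidates, and validate, producing one report bundle.

#' Pipeline run configuration
#'
#' Collects every module threshold in one validated object. Unknown
#' arguments are rejected so typos cannot silently fall back to defaults.
#'
#' @param mode `"simulate"` (generate inputs from `sim`) or `"real_input"`
#'   (caller supplies tables to [run_discovery()]).
#' @param noise_floor Volatile detection floor (normalized response;
#'   default 0.02).
#' @param rel_tol Relative tolerance for trend classification
#'   (default 0.2).
#' @param detect_threshold Expression detection threshold, RPKM
#'   (default 1).
#' @param min_rpkm Parental-comparison abundance filter (default 10).
#' @param parent_fold Parental overexpression fold (default 5).
#' @param fold_threshold Final pairwise filter fold (default 4; the report
#'   also lists candidate counts at 2 and 3).
#' @param pseudocount RPKM pseudocount in fold ratios (default 0.1).
#' @param min_nonref_frac,min_depth,min_genotypes SNP criteria (defaults
#'   0.95, 10, 2).
#' @param seed Master seed.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "real_input"), noise_floor = 0.02,
                       rel_tol = 0.2, detect_threshold = 1, min_rpkm = 10,
                       parent_fold = 5, fold_threshold = 4, pseudocount = 0.1,
                       min_nonref_frac = 0.95, min_depth = 10,
                       min_genotypes = 2, seed = 1L, sim = NULL) {
  mode <- match.arg(mode)
  assert_scalar_number(noise_floor, "noise_floor", min = 0)
  assert_scalar_number(fold_threshold, "fold_threshold", min = 1,
                       strict_min = TRUE)
  sim <- sim %||% sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(list(mode = mode, noise_floor = noise_floor, rel_tol = rel_tol,
                 detect_threshold = detect_threshold, min_rpkm = min_rpkm,
                 parent_fold = parent_fold, fold_threshold = fold_threshold,
                 pseudocount = pseudocount,
                 min_nonref_frac = min_nonref_frac, min_depth = min_depth,
                 min_genotypes = min_genotypes, seed = as.integer(seed),
                 sim = sim),
            class = "run_config")
}

#' Run the full discovery workflow
#'
#' Phenotype the volatile tables, pool genotypes by producer status, apply
#' the pairwise fold filter (reported at folds 2, 3 and the configured
#' threshold) plus the presence/absence-correlation screen, then validate
#' with the marker, SSR, segregation and qPCR statistics and filter the
#' SNP pileups. In `"simulate"` mode all inputs come from
#' [simulate_population()] under the configured seed.
#'
#' @param config A [run_config()].
#' @param data For `mode = "real_input"`, a list with elements
#'   `expression` ([expression_matrix()]), `volatiles`, `markers`, `ssr`,
#'   `qpcr`, `pileups` as documented in the readers; ignored in simulate
#'   mode.
#' @param out_dir Optional directory; when given, the phenotype, candidate
#'   and VCF outputs are written there.
#' @return List of class `report_bundle`; see Details.
#' @details The bundle contains `phenotypes`, `pools`, `parental`,
#'   `candidate_counts` (candidates surviving folds 2/3/threshold),
#'   `candidates` (final screen output), `top_parent_genes`,
#'   `marker_concordance`, `ssr_association`, `segregation`
#'   (producer:non-producer vs 1:1), `qpcr_panel` (per-genotype fold vs
#'   the producer parent), `snp_calls`, and a `provenance` block (seed,
#'   thresholds, package version).
#' @export
run_discovery <- function(config = run_config(), data = NULL,
                          out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    data <- simulate_population(config$sim)
  } else {
    needed <- c("expression", "volatiles", "markers", "ssr", "qpcr", "pileups")
    missing <- setdiff(needed, names(data %||% list()))
    if (length(missing)) {
      stop("real_input mode needs data element(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  em <- data$expression
  message(sprintf("[phenotype] %d peak rows, %d genotypes",
                  nrow(data$volatiles), length(unique(data$volatiles$genotype_id))))
  phenotypes <- phenotype_volatiles(data$volatiles, config$noise_floor,
                                    config$rel_tol)
  producers <- phenotypes$genotype_id[phenotypes$status == "PRODUCER"]
  nonproducers <- phenotypes$genotype_id[phenotypes$status == "NONPRODUCER"]
  if (length(producers) == 0L || length(nonproducers) == 0L) {
    stop("cannot pool: need at least one producer and one non-producer call",
         call. = FALSE)
  }
  absent <- setdiff(c(producers, nonproducers), colnames(em$counts))
  if (length(absent)) {
    stop("phenotyped genotype(s) missing from expression data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pools <- phenotype_pools(producers, nonproducers)
  rpkm <- compute_rpkm(em)
  message(sprintf("[bulk] pools: %d producers / %d non-producers over %d genes",
                  length(producers), length(nonproducers), nrow(rpkm)))
  parental <- if (all(c("parent_producer", "parent_nonproducer") %in%
                      colnames(rpkm))) {
    parental_comparison(rpkm, "parent_producer", "parent_nonproducer",
                        min_rpkm = config$min_rpkm, fold = config$parent_fold,
                        detect_threshold = config$detect_threshold)
  } else NULL
  folds <- sort(unique(c(2, 3, config$fold_threshold)))
  sweep_counts <- vapply(folds, function(f) {
    nrow(pairwise_candidate_filter(rpkm, pools, fold_threshold = f,
                                   pseudocount = config$pseudocount,
                                   detect_threshold = config$detect_threshold))
  }, integer(1L))
  candidates <- pairwise_candidate_filter(
    rpkm, pools, fold_threshold = config$fold_threshold,
    pseudocount = config$pseudocount,
    detect_threshold = config$detect_threshold)
  final <- presence_correlation_screen(candidates)
  message(sprintf("[filter] %d candidates at fold %g; %d after presence screen",
                  nrow(candidates), config$fold_threshold, nrow(final)))
  top_genes <- if (!is.null(parental)) {
    rank_by_parent_abundance(rpkm, "parent_producer", "parent_nonproducer",
                             k = 12L,
                             detect_threshold = config$detect_threshold)
  } else NULL
  concordance <- marker_concordance(data$markers, phenotypes)
  ssr_assoc <- ssr_allele_association(data$ssr, phenotypes)
  progeny_status <- phenotypes$status[!phenotypes$genotype_id %in%
                                        c("parent_producer", "parent_nonproducer")]
  seg <- chi_square_ratio(c(producer = sum(progeny_status == "PRODUCER"),
                            nonproducer = sum(progeny_status == "NONPRODUCER")),
                          c(1, 1))
  qpcr_panel <- NULL
  if (!is.null(data$qpcr)) {
    calibrator <- if ("parent_producer" %in% data$qpcr$condition) {
      "parent_producer"
    } else unique(data$qpcr$condition)[1L]
    conds <- setdiff(unique(data$qpcr$condition), calibrator)
    qpcr_panel <- do.call(rbind, lapply(conds, function(cond) {
      fc <- ddct_fold_change(data$qpcr, cond, calibrator)
      data.frame(condition = cond, fold = fc$fold,
                 no_amplification = fc$no_amplification,
                 stringsAsFactors = FALSE)
    }))
  }
  snp_calls <- filter_snps(data$pileups,
                           min_nonref_frac = config$min_nonref_frac,
                           min_depth = config$min_depth,
                           min_genotypes = config$min_genotypes)
  message(sprintf("[snps] %d of %d sites emitted",
                  nrow(snp_calls), length(unique(paste(data$pileups$chrom,
                                                       data$pileups$pos)))))
  bundle <- structure(list(
    phenotypes = phenotypes,
    pools = pools,
    parental = parental,
    candidate_counts = stats::setNames(sweep_counts, paste0("fold_", folds)),
    candidates = final,
    candidates_prescreen = candidates,
    top_parent_genes = top_genes,
    marker_concordance = concordance,
    ssr_association = ssr_assoc,
    segregation = seg,
    qpcr_panel = qpcr_panel,
    snp_calls = snp_calls,
    provenance = list(seed = config$seed, mode = config$mode,
                      fold_threshold = config$fold_threshold,
                      detect_threshold = config$detect_threshold,
                      noise_floor = config$noise_floor,
                      pseudocount = config$pseudocount,
                      package_version = as.character(utils::packageVersion("lactomap")))
  ), class = "report_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotype_tsv(phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_table_checked(final, file.path(out_dir, "candidates.tsv"))
    all_ids <- sort(unique(data$pileups$genotype_id))
    write_vcf(snp_calls, all_ids, file.path(out_dir, "snps.vcf"))
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Discovery report\n")
  cat(sprintf("  pools: %d producers / %d non-producers\n",
              length(x$pools$producers), length(x$pools$nonproducers)))
  cat("  candidates surviving the pairwise filter: ",
      paste(sprintf("%s: %d", names(x$candidate_counts), x$candidate_counts),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  after 100%% presence/absence screen: %d\n",
              nrow(x$candidates)))
  if (nrow(x$candidates)) {
    cat(sprintf("    %s (min pairwise fold %.3g)\n", x$candidates$gene_id,
                x$candidates$min_pairwise_fold))
  }
  cat(sprintf("  marker concordance: %.1f%% (p = %.3g)\n",
              100 * x$marker_concordance$concordance,
              x$marker_concordance$p_value))
  cat(sprintf("  segregation chi-square vs 1:1: %.3g (p = %.3g)\n",
              x$segregation$chi_square, x$segregation$p_value))
  cat(sprintf("  SNP calls emitted: %d\n", nrow(x$snp_calls)))
  invisible(x)
}
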