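# RPKM quantification, parental comparison and the in-silico bulked-segregant
# candidate filter: the discovery computation at the centre of the package.

#' Construct an expression matrix container
#'
#' Holds gene-level raw counts (gene x genotype), per-gene transcript
#' lengths and per-genotype library sizes (total mapped reads). All RPKM
#' work starts from this container.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), genotypes in columns (colnames = genotype ids).
#' @param gene_lengths Positive lengths in bp, one per gene, in row order
#'   (or named by gene id).
#' @param library_sizes Positive totals of mapped reads per genotype, in
#'   column order (or named by genotype id). If `NULL`, column sums of
#'   `counts` are used.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and genotype colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate genotype ids", call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(names(gene_lengths))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths))) {
    stop("gene_lengths must cover every gene in the matrix", call. = FALSE)
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  } else if (!is.null(names(library_sizes))) {
    library_sizes <- library_sizes[colnames(counts)]
  }
  if (length(library_sizes) != ncol(counts) || any(is.na(library_sizes))) {
    stop("library_sizes must cover every genotype in the matrix", call. = FALSE)
  }
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  structure(list(
    counts = counts,
    gene_lengths = stats::setNames(as.numeric(gene_lengths), rownames(counts)),
    library_sizes = stats::setNames(as.numeric(library_sizes), colnames(counts))
  ), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d genotypes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  library sizes: %s reads (median %.3g)\n",
              paste(format(range(x$library_sizes), big.mark = ","), collapse = "-"),
              stats::median(x$library_sizes)))
  invisible(x)
}

#' Compute RPKM from raw counts
#'
#' RPKM (reads per kilobase of transcript per million mapped reads)
#' normalizes counts for transcript length and sequencing depth:
#' `RPKM[g, s] = counts[g, s] * 1e9 / (library_sizes[s] * gene_lengths[g])`.
#' Zeros are preserved exactly, which matters for the presence/absence
#' logic downstream.
#'
#' @param em An [expression_matrix()].
#' @return Numeric matrix of RPKM values with the same dimnames as the
#'   counts.
#' @export
compute_rpkm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  sweep(em$counts / em$gene_lengths, 2L, em$library_sizes, `/`) * 1e9
}

#' Presence/absence detection flags
#'
#' A gene is called detected in a genotype when its RPKM strictly exceeds
#' the detection threshold. The threshold operationalizes the qualitative
#' "not detected" of heat-map style presence/absence screens.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param detect_threshold Detection threshold in RPKM units (`>= 0`,
#'   default 1).
#' @return Logical matrix with the dimnames of `rpkm`.
#' @export
detection_flags <- function(rpkm, detect_threshold = 1) {
  assert_scalar_number(detect_threshold, "detect_threshold", min = 0)
  rpkm > detect_threshold
}

#' Phenotype pools for in-silico bulking
#'
#' @param producers Genotype ids ever producing the volatile.
#' @param nonproducers Genotype ids never producing it.
#' @return An object of class `phenotype_pools`.
#' @export
phenotype_pools <- function(producers, nonproducers) {
  producers <- as.character(producers)
  nonproducers <- as.character(nonproducers)
  if (length(producers) == 0L || length(nonproducers) == 0L) {
    stop("both phenotype pools must be non-empty", call. = FALSE)
  }
  if (length(intersect(producers, nonproducers))) {
    stop("phenotype pools overlap: ",
         paste(intersect(producers, nonproducers), collapse = ", "),
         call. = FALSE)
  }
  structure(list(producers = producers, nonproducers = nonproducers),
            class = "phenotype_pools")
}

#' @keywords internal
#' @noRd
check_pools_in_matrix <- function(pools, rpkm) {
  stopifnot(inherits(pools, "phenotype_pools"))
  miss <- setdiff(c(pools$producers, pools$nonproducers), colnames(rpkm))
  if (length(miss)) {
    stop("pool genotype(s) absent from expression data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(pools)
}

#' Compare the parental transcriptomes
#'
#' Restricted to transcripts with RPKM above `min_rpkm` in at least one
#' parent, classifies each as unique to a parent (detected in one,
#' undetected in the other) or overexpressed (detected in both, at least
#' `fold`-fold higher in one).
#'
#' @param rpkm RPKM matrix.
#' @param parent_a,parent_b Genotype ids of the two parents.
#' @param min_rpkm Abundance filter: considered transcripts have
#'   RPKM > `min_rpkm` in at least one parent (default 10).
#' @param fold Overexpression ratio, inclusive (default 5).
#' @param detect_threshold Detection threshold in RPKM for the unique /
#'   undetected calls (default 1).
#' @return List of class `parental_comparison` with gene-id vectors
#'   `unique_to_a`, `unique_to_b`, `overexpressed_a`, `overexpressed_b`
#'   and the thresholds used.
#' @export
parental_comparison <- function(rpkm, parent_a, parent_b, min_rpkm = 10,
                                fold = 5, detect_threshold = 1) {
  for (p in c(parent_a, parent_b)) {
    if (!p %in% colnames(rpkm)) {
      stop("unknown genotype id: ", p, call. = FALSE)
    }
  }
  a <- rpkm[, parent_a]
  b <- rpkm[, parent_b]
  considered <- a > min_rpkm | b > min_rpkm
  det_a <- a > detect_threshold
  det_b <- b > detect_threshold
  genes <- rownames(rpkm)
  structure(list(
    unique_to_a = genes[considered & det_a & !det_b],
    unique_to_b = genes[considered & det_b & !det_a],
    overexpressed_a = genes[considered & det_a & det_b & a >= fold * b],
    overexpressed_b = genes[considered & det_a & det_b & b >= fold * a],
    parent_a = parent_a, parent_b = parent_b,
    min_rpkm = min_rpkm, fold = fold, detect_threshold = detect_threshold
  ), class = "parental_comparison")
}

#' @export
print.parental_comparison <- function(x, ...) {
  cat(sprintf("Parental comparison (%s vs %s; RPKM > %g in >= 1 parent):\n",
              x$parent_a, x$parent_b, x$min_rpkm))
  cat(sprintf("  unique to %s: %d | unique to %s: %d\n",
              x$parent_a, length(x$unique_to_a),
              x$parent_b, length(x$unique_to_b)))
  cat(sprintf("  >= %g-fold in %s: %d | in %s: %d\n", x$fold,
              x$parent_a, length(x$overexpressed_a),
              x$parent_b, length(x$overexpressed_b)))
  invisible(x)
}

#' All-pairs fold-change candidate filter over phenotype pools
#'
#' The bulked-segregant core: a gene survives only if it is more than
#' `fold_threshold`-fold higher in EVERY producer than in EVERY
#' non-producer, i.e. for every pair (p, q) of a producer and a
#' non-producer, `(RPKM[g, p] + pseudocount) / (RPKM[g, q] + pseudocount)
#' > fold_threshold`. Because the ratio is monotone, the binding pair is
#' (lowest producer, highest non-producer), which is what gets reported as
#' `min_pairwise_fold`. The pseudocount keeps zero denominators finite
#' without reordering genes.
#'
#' @param rpkm RPKM matrix.
#' @param pools A [phenotype_pools()] object; every id must be a column of
#'   `rpkm`.
#' @param fold_threshold Strict fold requirement, `> 1` (default 4; the
#'   screen is usually swept over 2-4).
#' @param pseudocount Added to both sides of each ratio (default 0.1 RPKM).
#' @param detect_threshold Detection threshold used to annotate
#'   presence/absence correlation (default 1 RPKM).
#' @return Data frame of surviving genes: `gene_id`, `min_pairwise_fold`,
#'   `producer_mean_rpkm`, `nonproducer_mean_rpkm`, `n_detected_producers`,
#'   `n_detected_nonproducers`, `perfect_correlation`, sorted by
#'   decreasing `min_pairwise_fold`.
#' @export
pairwise_candidate_filter <- function(rpkm, pools, fold_threshold = 4,
                                      pseudocount = 0.1,
                                      detect_threshold = 1) {
  check_pools_in_matrix(pools, rpkm)
  assert_scalar_number(fold_threshold, "fold_threshold", min = 1,
                       strict_min = TRUE)
  assert_scalar_number(pseudocount, "pseudocount", min = 0)
  prod <- rpkm[, pools$producers, drop = FALSE]
  nonp <- rpkm[, pools$nonproducers, drop = FALSE]
  min_p <- apply(prod, 1L, min)
  max_q <- apply(nonp, 1L, max)
  min_fold <- (min_p + pseudocount) / (max_q + pseudocount)
  keep <- min_fold > fold_threshold
  flags <- detection_flags(rpkm, detect_threshold)
  det_p <- rowSums(flags[, pools$producers, drop = FALSE])
  det_q <- rowSums(flags[, pools$nonproducers, drop = FALSE])
  out <- data.frame(
    gene_id = rownames(rpkm)[keep],
    min_pairwise_fold = min_fold[keep],
    producer_mean_rpkm = rowMeans(prod)[keep],
    nonproducer_mean_rpkm = rowMeans(nonp)[keep],
    n_detected_producers = det_p[keep],
    n_detected_nonproducers = det_q[keep],
    perfect_correlation = (det_p[keep] == length(pools$producers)) &
      (det_q[keep] == 0L),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$min_pairwise_fold, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool-mean variant of the candidate filter
#'
#' Sensitivity-analysis mode: compares pool means instead of all pairs.
#' More permissive than [pairwise_candidate_filter()] because one high
#' non-producer can be averaged away.
#'
#' @inheritParams pairwise_candidate_filter
#' @return Data frame as in [pairwise_candidate_filter()] with
#'   `pool_mean_fold` in place of `min_pairwise_fold`.
#' @export
poolmean_candidate_filter <- function(rpkm, pools, fold_threshold = 4,
                                      pseudocount = 0.1,
                                      detect_threshold = 1) {
  check_pools_in_matrix(pools, rpkm)
  assert_scalar_number(fold_threshold, "fold_threshold", min = 1,
                       strict_min = TRUE)
  mean_p <- rowMeans(rpkm[, pools$producers, drop = FALSE])
  mean_q <- rowMeans(rpkm[, pools$nonproducers, drop = FALSE])
  fold <- (mean_p + pseudocount) / (mean_q + pseudocount)
  keep <- fold > fold_threshold
  flags <- detection_flags(rpkm, detect_threshold)
  det_p <- rowSums(flags[, pools$producers, drop = FALSE])
  det_q <- rowSums(flags[, pools$nonproducers, drop = FALSE])
  out <- data.frame(
    gene_id = rownames(rpkm)[keep],
    pool_mean_fold = fold[keep],
    producer_mean_rpkm = mean_p[keep],
    nonproducer_mean_rpkm = mean_q[keep],
    n_detected_producers = det_p[keep],
    n_detected_nonproducers = det_q[keep],
    perfect_correlation = (det_p[keep] == length(pools$producers)) &
      (det_q[keep] == 0L),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$pool_mean_fold, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain candidates whose detection correlates 100% with phenotype
#'
#' The final screen: keep exactly those candidates detected in all
#' producers and undetected in all non-producers.
#'
#' @param candidates Output of [pairwise_candidate_filter()].
#' @return The subset with `perfect_correlation = TRUE`.
#' @export
presence_correlation_screen <- function(candidates) {
  assert_columns(candidates, "perfect_correlation", "candidate table")
  out <- candidates[candidates$perfect_correlation, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by abundance in the producer parent
#'
#' Among genes undetected in the non-producer parent, returns the top `k`
#' by RPKM in the producer parent (ties broken by gene id), the ordering
#' used to shortlist abundant producer-specific transcripts.
#'
#' @param rpkm RPKM matrix.
#' @param producer_parent,nonproducer_parent Parental genotype ids.
#' @param k Number of genes to return (truncated to the eligible set).
#' @param detect_threshold Detection threshold in RPKM (default 1).
#' @return Data frame: `gene_id`, `producer_parent_rpkm`, in rank order.
#' @export
rank_by_parent_abundance <- function(rpkm, producer_parent,
                                     nonproducer_parent, k = 12L,
                                     detect_threshold = 1) {
  assert_scalar_number(k, "k", min = 1)
  for (p in c(producer_parent, nonproducer_parent)) {
    if (!p %in% colnames(rpkm)) stop("unknown genotype id: ", p, call. = FALSE)
  }
  eligible <- rpkm[, nonproducer_parent] <= detect_threshold
  g <- rownames(rpkm)[eligible]
  v <- rpkm[eligible, producer_parent]
  ord <- order(-v, g)
  take <- seq_len(min(k, length(g)))
  data.frame(gene_id = g[ord][take],
             producer_parent_rpkm = unname(v[ord][take]),
             stringsAsFactors = FALSE)
}
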