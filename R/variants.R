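# SNP filtering on per-site, per-genotype pileup summaries, and a minimal
# VCF 4.2 writer for the surviving calls.

#' Filter candidate SNP sites by depth, allele fraction and recurrence
#'
#' A genotype supports a site when its read depth is at least `min_depth`
#' AND its non-reference read fraction is at least `min_nonref_frac`; a
#' site is emitted when at least `min_genotypes` genotypes support it.
#' Both per-genotype thresholds are inclusive ("10 or greater",
#' "95% minimum").
#'
#' @param sites Long-format data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `genotype_id`, `depth`, `nonref_count` (one row per site x
#'   genotype).
#' @param min_nonref_frac Minimum non-reference read fraction, in (0, 1]
#'   (default 0.95).
#' @param min_depth Minimum read depth (default 10).
#' @param min_genotypes Minimum number of supporting genotypes (default 2).
#' @return Data frame of emitted calls sorted by (`chrom`, `pos`):
#'   `chrom`, `pos`, `ref`, `alt`, `n_passing`, `passing_genotypes`
#'   (comma-separated ids).
#' @export
filter_snps <- function(sites, min_nonref_frac = 0.95, min_depth = 10,
                        min_genotypes = 2) {
  assert_columns(sites, c("chrom", "pos", "ref", "alt", "genotype_id",
                          "depth", "nonref_count"), "pileup table")
  if (!is.numeric(min_nonref_frac) || min_nonref_frac <= 0 || min_nonref_frac > 1) {
    stop("`min_nonref_frac` must lie in (0, 1]", call. = FALSE)
  }
  assert_scalar_number(min_depth, "min_depth", min = 1)
  assert_scalar_number(min_genotypes, "min_genotypes", min = 1)
  bad <- sites$nonref_count > sites$depth | sites$nonref_count < 0 |
    sites$depth < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed pileup at %s:%d (%s): nonref_count %d vs depth %d",
                 sites$chrom[i], sites$pos[i], sites$genotype_id[i],
                 sites$nonref_count[i], sites$depth[i]), call. = FALSE)
  }
  pass <- sites$depth >= min_depth &
    sites$depth > 0 & sites$nonref_count / pmax(sites$depth, 1L) >= min_nonref_frac
  key <- paste(sites$chrom, sites$pos, sep = ":")
  out <- do.call(rbind, lapply(split(seq_len(nrow(sites)), key), function(idx) {
    p <- idx[pass[idx]]
    if (length(p) < min_genotypes) return(NULL)
    data.frame(chrom = sites$chrom[idx[1L]],
               pos = sites$pos[idx[1L]],
               ref = sites$ref[idx[1L]],
               alt = sites$alt[idx[1L]],
               n_passing = length(p),
               passing_genotypes = paste(sort(sites$genotype_id[p]),
                                         collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n_passing = integer(),
                      passing_genotypes = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write SNP calls as a minimal VCF 4.2 document
#'
#' One record per emitted site, 1-based coordinates as in the input,
#' `NPASS` (number of genotypes passing the per-genotype criteria) in
#' INFO, and a per-sample `PA` pass flag (1/0) in FORMAT.
#'
#' @param calls Output of [filter_snps()], sorted by (`chrom`, `pos`).
#' @param sample_ids All genotype ids to report columns for.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_ids, path) {
  assert_columns(calls, c("chrom", "pos", "ref", "alt", "n_passing",
                          "passing_genotypes"), "call table")
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (chrom, pos) before writing VCF",
           call. = FALSE)
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lactomap_filter_snps",
    "##INFO=<ID=NPASS,Number=1,Type=Integer,Description=\"Number of genotypes passing depth and non-reference-fraction criteria\">",
    "##FORMAT=<ID=PA,Number=1,Type=Integer,Description=\"1 if this genotype passed the per-genotype SNP criteria at this site\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  records <- vapply(seq_len(nrow(calls)), function(i) {
    passing <- strsplit(calls$passing_genotypes[i], ",", fixed = TRUE)[[1L]]
    flags <- as.integer(sample_ids %in% passing)
    paste(c(calls$chrom[i], calls$pos[i], ".", calls$ref[i], calls$alt[i],
            ".", "PASS", sprintf("NPASS=%d", calls$n_passing[i]), "PA",
            flags), collapse = "\t")
  }, character(1L))
  writeLines(c(header, records), path)
  invisible(path)
}
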