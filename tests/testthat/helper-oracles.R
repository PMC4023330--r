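# Literal brute-force reference implementations used as independent oracles.
# Deliberately written as naive loops over the rule text, with no shared code
# paths with the package internals.

oracle_pairwise_filter <- function(rpkm, producers, nonproducers,
                                   fold_threshold, pseudocount) {
  keep <- character()
  for (g in rownames(rpkm)) {
    ok <- TRUE
    for (p in producers) {
      for (q in nonproducers) {
        r <- (rpkm[g, p] + pseudocount) / (rpkm[g, q] + pseudocount)
        if (!(r > fold_threshold)) ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, g)
  }
  keep
}

oracle_filter_snps <- function(sites, min_nonref_frac, min_depth,
                               min_genotypes) {
  keys <- unique(paste(sites$chrom, sites$pos, sep = ":"))
  emitted <- character()
  for (k in keys) {
    idx <- which(paste(sites$chrom, sites$pos, sep = ":") == k)
    n_pass <- 0L
    for (i in idx) {
      if (sites$depth[i] >= min_depth &&
          sites$depth[i] > 0 &&
          sites$nonref_count[i] / sites$depth[i] >= min_nonref_frac) {
        n_pass <- n_pass + 1L
      }
    }
    if (n_pass >= min_genotypes) emitted <- c(emitted, k)
  }
  sort(emitted)
}

oracle_parental <- function(rpkm, a, b, min_rpkm, fold, detect_threshold) {
  res <- list(unique_to_a = character(), unique_to_b = character(),
              overexpressed_a = character(), overexpressed_b = character())
  for (g in rownames(rpkm)) {
    va <- rpkm[g, a]; vb <- rpkm[g, b]
    if (!(va > min_rpkm || vb > min_rpkm)) next
    da <- va > detect_threshold; db <- vb > detect_threshold
    if (da && !db) res$unique_to_a <- c(res$unique_to_a, g)
    if (db && !da) res$unique_to_b <- c(res$unique_to_b, g)
    if (da && db && va >= fold * vb) {
      res$overexpressed_a <- c(res$overexpressed_a, g)
    }
    if (da && db && vb >= fold * va) {
      res$overexpressed_b <- c(res$overexpressed_b, g)
    }
  }
  res
}

oracle_concordance <- function(amplicon, producer) {
  n_match <- 0L
  for (i in seq_along(amplicon)) {
    if ((amplicon[i] && producer[i]) || (!amplicon[i] && !producer[i])) {
      n_match <- n_match + 1L
    }
  }
  n_match / length(amplicon)
}

# small random fixture builders -------------------------------------------

random_rpkm <- function(n_genes, genotype_ids, max_rpkm = 60) {
  m <- matrix(round(stats::runif(n_genes * length(genotype_ids), 0, max_rpkm), 2),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), genotype_ids))
  # sprinkle zeros so the presence/absence edge cases are exercised
  m[stats::runif(length(m)) < 0.3] <- 0
  m
}

random_pileup <- function(n_sites, n_genotypes) {
  ids <- sprintf("G%02d", seq_len(n_genotypes))
  do.call(rbind, lapply(seq_len(n_sites), function(s) {
    depth <- stats::rpois(n_genotypes, 12)
    data.frame(chrom = "chr1", pos = s, ref = "A", alt = "G",
               genotype_id = ids, depth = depth,
               nonref_count = vapply(depth, function(d) {
                 if (d == 0) 0L else sample(0:d, 1L)
               }, integer(1L)),
               stringsAsFactors = FALSE)
  }))
}
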