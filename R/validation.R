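# Validation statistics: comparative-CT fold change, chi-square segregation
# tests, PCR-marker concordance and SSR allele association.

#' Relative expression by the comparative-CT method
#'
#' Computes 2^(-ddCT) relative expression of a target gene against a
#' housekeeping control, comparing a sample condition to a calibrator
#' condition, assuming 100% amplification efficiency. Per condition,
#' dCT = mean(CT_target) - mean(CT_housekeeping); ddCT = dCT_sample -
#' dCT_calibrator; fold = 2^(-ddCT). The replicate SD of the sample dCT is
#' propagated as sqrt(sd_target^2 + sd_housekeeping^2).
#'
#' A sample whose target never amplifies (all CT missing) reflects absence
#' of the transcript, not low expression: the fold is reported as 0 with
#' `no_amplification = TRUE`, never imputed to a maximum cycle.
#'
#' @param measurements Long data frame with columns `condition`, `gene`
#'   (`"target"` or `"housekeeping"`), `replicate`, `ct` (NA = no
#'   amplification).
#' @param sample,calibrator Condition labels to compare.
#' @return List of class `fold_change_result`: `fold`, `ddct`, `sd_ct`
#'   (cycles), `sd_fold_upper`/`sd_fold_lower` (fold at ddct -/+ sd),
#'   `no_amplification`.
#' @export
ddct_fold_change <- function(measurements, sample, calibrator) {
  assert_columns(measurements, c("condition", "gene", "ct"), "qPCR table")
  get <- function(cond, gene) {
    ct <- measurements$ct[measurements$condition == cond &
                            measurements$gene == gene]
    if (length(ct) == 0L) {
      stop(sprintf("no %s CT data for condition '%s'", gene, cond),
           call. = FALSE)
    }
    ct
  }
  hk_s <- get(sample, "housekeeping")
  hk_c <- get(calibrator, "housekeeping")
  if (all(is.na(hk_s)) || all(is.na(hk_c))) {
    stop("housekeeping gene failed to amplify; cannot normalize",
         call. = FALSE)
  }
  tg_s <- get(sample, "target")
  tg_c <- get(calibrator, "target")
  if (all(is.na(tg_s))) {
    return(structure(list(fold = 0, ddct = NA_real_, sd_ct = NA_real_,
                          sd_fold_upper = NA_real_, sd_fold_lower = NA_real_,
                          no_amplification = TRUE),
                     class = "fold_change_result"))
  }
  m <- function(x) mean(x, na.rm = TRUE)
  s <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1L) stats::sd(x) else 0
  }
  dct_s <- m(tg_s) - m(hk_s)
  dct_c <- m(tg_c) - m(hk_c)
  ddct <- dct_s - dct_c
  sd_ct <- sqrt(s(tg_s)^2 + s(hk_s)^2)
  structure(list(fold = 2^(-ddct), ddct = ddct, sd_ct = sd_ct,
                 sd_fold_upper = 2^(-(ddct - sd_ct)),
                 sd_fold_lower = 2^(-(ddct + sd_ct)),
                 no_amplification = FALSE),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  if (x$no_amplification) {
    cat("Comparative CT: target not amplified in sample (fold 0)\n")
  } else {
    cat(sprintf("Comparative CT: fold = %.3g (ddCT = %.3g +/- %.3g cycles; fold range %.3g-%.3g)\n",
                x$fold, x$ddct, x$sd_ct, x$sd_fold_lower, x$sd_fold_upper))
  }
  invisible(x)
}

#' Chi-square goodness-of-fit test against an expected segregation ratio
#'
#' Pearson's test of observed category counts against a Mendelian ratio
#' (e.g. 1:1 for a simplex dominant locus), via [stats::chisq.test()]
#' without continuity correction.
#'
#' @param observed Named or unnamed non-negative category counts.
#' @param expected_ratio Expected ratio, same length as `observed` (e.g.
#'   `c(1, 1)`).
#' @return List of class `segregation_test`: `observed`, `expected`,
#'   `chi_square`, `df`, `p_value`.
#' @export
chi_square_ratio <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio)) {
    stop("observed counts and expected ratio differ in length", call. = FALSE)
  }
  if (any(expected_ratio <= 0)) {
    stop("all expected ratio entries must be > 0", call. = FALSE)
  }
  if (sum(observed) <= 0) stop("total observed count is 0", call. = FALSE)
  p <- expected_ratio / sum(expected_ratio)
  ct <- suppressWarnings(stats::chisq.test(observed, p = p, correct = FALSE))
  structure(list(observed = observed, expected = sum(observed) * p,
                 chi_square = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value)),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Chi-square vs ratio %s: X^2 = %.4g, df = %d, p = %.4g\n",
              paste(round(x$expected / min(x$expected), 2), collapse = ":"),
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Concordance between a dominant PCR marker and the volatile phenotype
#'
#' Compares amplicon presence with producer status genotype by genotype.
#' Genotypes whose positive PCR control failed, or whose phenotype is
#' INSUFFICIENT_DATA, are excluded. Alongside the concordance fraction and
#' the discordant ids, a 2x2 cosegregation test is reported: Pearson
#' chi-square (no continuity correction) for non-degenerate tables; for a
#' degenerate table (a zero margin, as under perfect cosegregation) the
#' chi-square is undefined and the reported p-value is `2 * 0.5^n`, the
#' probability that a phenotype-independent even-odds presence/absence
#' marker matches the phenotype in all `n` genotypes in either polarity.
#'
#' @param markers Data frame: `genotype_id`, `amplicon_present` (logical),
#'   `control_present` (logical).
#' @param phenotypes Data frame: `genotype_id`, `status` (`"PRODUCER"`,
#'   `"NONPRODUCER"` or `"INSUFFICIENT_DATA"`).
#' @return List of class `marker_concordance`: `concordance`, `n_compared`,
#'   `discordant` (genotype ids), `table` (2x2), `chi_square`, `p_value`,
#'   `p_method`.
#' @export
marker_concordance <- function(markers, phenotypes) {
  assert_columns(markers, c("genotype_id", "amplicon_present",
                            "control_present"), "marker table")
  assert_columns(phenotypes, c("genotype_id", "status"), "phenotype table")
  d <- merge(markers, phenotypes, by = "genotype_id")
  d <- d[d$control_present & d$status %in% c("PRODUCER", "NONPRODUCER"), ,
         drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no genotypes with both a valid marker assay and a phenotype call",
         call. = FALSE)
  }
  is_producer <- d$status == "PRODUCER"
  match_ok <- d$amplicon_present == is_producer
  tab <- table(factor(d$amplicon_present, levels = c(FALSE, TRUE)),
               factor(is_producer, levels = c(FALSE, TRUE)),
               dnn = c("amplicon", "producer"))
  # a zero margin or a perfectly (anti)concordant table leaves the chi-square
  # approximation undefined or meaningless
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L) ||
    all(match_ok) || !any(match_ok)
  if (degenerate) {
    chi <- NA_real_
    p <- 2 * 0.5^nrow(d)
    method <- "exact_binomial_perfect_cosegregation"
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic)
    p <- unname(ct$p.value)
    method <- "pearson_chi_square"
  }
  structure(list(concordance = mean(match_ok), n_compared = nrow(d),
                 discordant = d$genotype_id[!match_ok], table = tab,
                 chi_square = chi, p_value = p, p_method = method),
            class = "marker_concordance")
}

#' @export
print.marker_concordance <- function(x, ...) {
  cat(sprintf("Marker-phenotype concordance: %.1f%% over %d genotypes (%d discordant)\n",
              100 * x$concordance, x$n_compared, length(x$discordant)))
  cat(sprintf("  cosegregation p = %.4g (%s)\n", x$p_value, x$p_method))
  invisible(x)
}

#' Per-allele association of an SSR marker with the volatile phenotype
#'
#' For each fragment size seen in the panel, reports its frequency among
#' producers and non-producers, whether it is monomorphic (present in every
#' genotype), and whether it perfectly predicts the phenotype (present in
#' all producers and no non-producer). Fragment sizes are compared as
#' exact integers; single-locus confirmatory screen, so no multiplicity
#' adjustment is applied.
#'
#' @param ssr Data frame: `genotype_id`, `alleles` (comma-separated
#'   fragment sizes in bp, or a list column of integer vectors).
#' @param phenotypes Data frame: `genotype_id`, `status`.
#' @return Data frame: `allele`, `freq_producers`, `freq_nonproducers`,
#'   `monomorphic`, `perfect_predictor`.
#' @export
ssr_allele_association <- function(ssr, phenotypes) {
  assert_columns(ssr, c("genotype_id", "alleles"), "SSR table")
  assert_columns(phenotypes, c("genotype_id", "status"), "phenotype table")
  d <- merge(ssr, phenotypes, by = "genotype_id")
  d <- d[d$status %in% c("PRODUCER", "NONPRODUCER"), , drop = FALSE]
  if (!any(d$status == "PRODUCER") || !any(d$status == "NONPRODUCER")) {
    stop("need >= 1 genotype in each phenotype class", call. = FALSE)
  }
  allele_sets <- if (is.list(d$alleles)) {
    lapply(d$alleles, as.integer)
  } else {
    lapply(strsplit(as.character(d$alleles), ","),
           function(x) as.integer(trimws(x)))
  }
  if (any(vapply(allele_sets, length, 1L) == 0L)) {
    stop("every genotype must carry at least one SSR allele", call. = FALSE)
  }
  alleles <- sort(unique(unlist(allele_sets)))
  is_producer <- d$status == "PRODUCER"
  out <- do.call(rbind, lapply(alleles, function(a) {
    has <- vapply(allele_sets, function(s) a %in% s, logical(1L))
    data.frame(allele = a,
               freq_producers = mean(has[is_producer]),
               freq_nonproducers = mean(has[!is_producer]),
               monomorphic = all(has),
               perfect_predictor = all(has[is_producer]) && !any(has[!is_producer]))
  }))
  rownames(out) <- NULL
  out
}
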