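# Generator contracts: Mendelian segregation, determinism, the deletion
# consistency invariant, and Monte-Carlo parameter recovery.

test_that("cross simulation follows Mendelian expectations and is deterministic", {
  locus <- locus_model()
  f1 <- simulate_cross(locus, "F1", n = 10000, seed = 202)
  frac <- mean(f1$carrier)
  sd3 <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), sd3)
  bc_np <- simulate_cross(locus, "BC1_to_nonproducer", n = 10000, seed = 203)
  expect_lt(abs(mean(bc_np$carrier) - 0.5), sd3)
  bc_p <- simulate_cross(locus, "BC1_to_producer", n = 10000, seed = 204)
  expect_lt(abs(mean(bc_p$carrier) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # same seed twice: identical output
  expect_identical(f1, simulate_cross(locus, "F1", n = 10000, seed = 202))
  expect_error(simulate_cross(locus, "F2", n = 10), "arg")
  # non-carriers never get a producer trend class
  expect_true(all(f1$trend_class[!f1$carrier] == "NONPRODUCER"))
  expect_true(all(f1$trend_class[f1$carrier] %in%
                    c("PEAK", "VALLEY", "DECREASE", "INCREASE")))
})

test_that("expression simulation models the deletion exactly and recovers the ripening fold", {
  cfg <- sim_config(n_genes = 60, causal_gene_index = 30, n_decoy_genes = 5,
                    seed = 9)
  panel <- simulate_panel(cfg)
  for (stage in c("green", "blushing", "ripe")) {
    em <- simulate_expression(panel, cfg, stage = stage)
    causal <- em$counts[causal_gene_id(cfg), ]
    expect_true(all(causal[!panel$carrier] == 0))
    expect_true(all(causal[panel$carrier] >= 0))
  }
  # determinism
  em1 <- simulate_expression(panel, cfg, stage = "ripe")
  em2 <- simulate_expression(panel, cfg, stage = "ripe")
  expect_identical(em1$counts, em2$counts)

  # Monte-Carlo recovery of the ripening factor: many replicate carrier
  # genotypes, ratio of mean causal counts at ripe vs blushing
  carriers <- data.frame(id = sprintf("c%04d", 1:2000), role = "F1",
                         carrier = TRUE, trend_class = "PEAK",
                         env_schedule = "b,b,b")
  ripe <- simulate_expression(carriers, cfg, stage = "ripe")
  blush <- simulate_expression(carriers, cfg, stage = "blushing")
  r <- ripe$counts[causal_gene_id(cfg), ]
  b <- blush$counts[causal_gene_id(cfg), ]
  ratio <- mean(r) / mean(b)
  se <- ratio * sqrt(var(r) / (mean(r)^2 * 2000) + var(b) / (mean(b)^2 * 2000))
  expect_lt(abs(ratio - cfg$ripening_fold), 3 * se)
})

test_that("decoy genes segregate independently of phenotype", {
  cfg <- sim_config(n_genes = 100, causal_gene_index = 50, n_decoy_genes = 20,
                    seed = 31)
  panel <- simulate_panel(cfg)
  em <- simulate_expression(panel, cfg, stage = "ripe")
  rpkm <- compute_rpkm(em)
  flags <- detection_flags(rpkm, 1)
  causal_pattern <- panel$carrier
  # under independent 0.5 assignment a decoy matches the carrier pattern in
  # all 16 genotypes (either polarity) with probability 2 * 0.5^16 each;
  # with 20 decoys the chance of any match is ~6e-4
  decoy_ids <- setdiff(rownames(rpkm)[rowSums(em$counts == 0) > 0],
                       causal_gene_id(cfg))
  n_matching <- sum(vapply(decoy_ids, function(g) {
    all(flags[g, ] == causal_pattern) || all(flags[g, ] == !causal_pattern)
  }, logical(1)))
  expect_equal(n_matching, 0)
})

test_that("volatile tables respect the deletion and trend-class structure", {
  cfg <- sim_config(seed = 17)
  panel <- simulate_panel(cfg)
  peaks <- simulate_volatile_tables(panel, cfg, n_harvests = 3)
  expect_error(simulate_volatile_tables(panel, cfg, n_harvests = 2), ">= 3")
  resp <- normalize_to_internal_standard(peaks$gd_area, peaks$is_area)
  noncar <- peaks$genotype_id %in% panel$id[!panel$carrier]
  expect_true(all(resp[noncar] <= cfg$volatile_baseline))
  expect_true(all(resp[!noncar] > cfg$volatile_baseline))
  # PEAK carriers have their harvest-2 mean strictly greatest
  series <- volatile_series(peaks)
  peak_ids <- panel$id[panel$carrier & panel$trend_class == "PEAK"]
  for (id in peak_ids) {
    v <- series$mean_response[series$genotype_id == id]
    expect_identical(which.max(v), 2L)
  }
  # determinism
  expect_identical(peaks, simulate_volatile_tables(panel, cfg, 3))
})

test_that("environment effect on carrier volatiles is recovered within 10%", {
  cfg <- sim_config(seed = 23)
  n <- 400
  mk <- function(env) data.frame(id = sprintf("%s%03d", env, 1:n), role = "F1",
                                 carrier = TRUE, trend_class = "PEAK",
                                 env_schedule = paste(rep(env, 3), collapse = ","))
  pa <- simulate_volatile_tables(mk("a"), cfg, 3)
  pb <- simulate_volatile_tables(mk("b"), cfg, 3)
  ra <- mean(normalize_to_internal_standard(pa$gd_area, pa$is_area))
  rb <- mean(normalize_to_internal_standard(pb$gd_area, pb$is_area))
  expect_lt(abs(rb / ra - cfg$env_effect_fold) / cfg$env_effect_fold, 0.10)
})

test_that("marker and SSR panels are fully linked to carrier status", {
  cfg <- sim_config(seed = 29)
  panel <- simulate_panel(cfg)
  mk <- simulate_marker_panel(panel, seed = 5)
  expect_identical(mk$markers$amplicon_present, panel$carrier)
  expect_true(all(mk$markers$control_present))
  sets <- strsplit(mk$ssr$alleles, ",")
  has205 <- vapply(sets, function(s) "205" %in% s, logical(1))
  has209 <- vapply(sets, function(s) "209" %in% s, logical(1))
  expect_identical(has205, panel$carrier)
  expect_true(all(has209))               # monomorphic allele: never empty sets
  expect_true(all(lengths(sets) >= 1))
})

test_that("pileup simulation plants passing sites at the requested rate", {
  cfg <- sim_config(seed = 37)
  sim <- simulate_pileups(10000, n_genotypes = 16, cfg = cfg, seed = 37,
                          frac_pass = 0.3)
  calls <- filter_snps(sim$sites)
  frac <- nrow(calls) / 10000
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # every planted site passes by construction
  planted_keys <- paste("chr1", which(sim$planted_pass) * 10L, sep = ":")
  emitted_keys <- paste(calls$chrom, calls$pos, sep = ":")
  expect_true(all(planted_keys %in% emitted_keys))
  # a site with zero depth everywhere can never pass
  zero <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T",
                     genotype_id = c("G01", "G02"), depth = 0L,
                     nonref_count = 0L)
  expect_equal(nrow(filter_snps(zero)), 0L)
})

test_that("simulated qPCR recovers the configured fold under the ddCT analysis", {
  cfg <- sim_config(ct_noise_sd = 0, seed = 41)
  panel <- simulate_panel(cfg)
  # zero CT noise: closed forms exactly
  fx1 <- simulate_qpcr(panel, cfg, design = "stage_pair", fold = 1)
  expect_equal(ddct_fold_change(fx1, "ripe", "blushing")$fold, 1,
               tolerance = 1e-12)
  fx2 <- simulate_qpcr(panel, cfg, design = "stage_pair", fold = 2)
  expect_equal(ddct_fold_change(fx2, "ripe", "blushing")$ddct, -1,
               tolerance = 1e-12)
  # noise 0.05 cycles, fold 21: mean recovered fold within 5%
  cfg2 <- sim_config(ct_noise_sd = 0.05, seed = 43)
  folds <- vapply(1:1000, function(i) {
    fx <- simulate_qpcr(panel, cfg2, design = "stage_pair", fold = 21,
                        seed = i)
    ddct_fold_change(fx, "ripe", "blushing")$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 21) / 21, 0.05)
  # genotype panel: non-carriers are no-amplification, fold 0
  fxp <- simulate_qpcr(panel, cfg, design = "genotype_panel")
  nc <- panel$id[!panel$carrier][1L]
  r <- ddct_fold_change(fxp, nc, "parent_producer")
  expect_equal(r$fold, 0)
  expect_true(r$no_amplification)
})

test_that("deletion consistency ties expression, volatiles, marker and SSR together", {
  cfg <- sim_config(n_genes = 200, causal_gene_index = 100, n_decoy_genes = 10,
                    seed = 47)
  pop <- simulate_population(cfg, n_pileup_sites = 10)
  causal_counts <- pop$expression$counts[causal_gene_id(cfg), ]
  resp <- normalize_to_internal_standard(pop$volatiles$gd_area,
                                         pop$volatiles$is_area)
  for (i in seq_len(nrow(pop$genotypes))) {
    id <- pop$genotypes$id[i]
    carrier <- pop$genotypes$carrier[i]
    expect_identical(causal_counts[[id]] > 0, carrier)
    expect_identical(pop$markers$amplicon_present[pop$markers$genotype_id == id],
                     carrier)
    expect_identical(grepl("(^|,)205(,|$)",
                           pop$ssr$alleles[pop$ssr$genotype_id == id]), carrier)
    gd <- resp[pop$volatiles$genotype_id == id]
    expect_identical(any(gd > cfg$volatile_baseline), carrier)
  }
})
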