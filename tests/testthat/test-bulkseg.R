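# RPKM, parental comparison and the bulked-segregant candidate filter.

toy_matrix <- function() {
  counts <- matrix(c(10, 0, 25, 5,
                     0, 8, 100, 3), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  expression_matrix(counts, gene_lengths = c(g1 = 1000, g2 = 2500),
                    library_sizes = c(s1 = 1e6, s2 = 2e6, s3 = 5e5, s4 = 1e6))
}

test_that("RPKM follows the formula and preserves zeros", {
  em <- toy_matrix()
  rpkm <- compute_rpkm(em)
  expect_equal(rpkm["g1", "s1"], 10)        # 10 reads / 1 kb / 1e6
  expect_equal(rpkm["g1", "s2"], 0)
  # element-wise oracle on a random matrix
  set.seed(5)
  counts <- matrix(rpois(50 * 8, 40), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:8)))
  lens <- sample(200:4000, 50)
  libs <- runif(8, 1e5, 1e6)
  em2 <- expression_matrix(counts, lens, libs)
  rpkm2 <- compute_rpkm(em2)
  for (i in sample(50, 10)) {
    for (j in sample(8, 4)) {
      expect_equal(rpkm2[i, j], counts[i, j] * 1e9 / (libs[j] * lens[i]),
                   tolerance = 1e-12)
    }
  }
  # conservation: mapping RPKM back to counts reproduces the column sums
  back <- sweep(rpkm2 * lens / 1e9, 2, libs, `*`)
  expect_equal(colSums(back), colSums(counts), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("expression_matrix validates its invariants", {
  counts <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(expression_matrix(counts, c(a = 0, b = 10)), "> 0")
  expect_error(expression_matrix(counts, c(a = 5, b = 10),
                                 c(x = 0, y = 1)), "> 0")
  expect_error(expression_matrix(matrix(1, 2, 2), c(5, 10)), "rownames")
  counts2 <- counts; counts2[1, 1] <- -1
  expect_error(expression_matrix(counts2, c(a = 5, b = 10)), ">= 0")
})

test_that("detection flags use a strict threshold", {
  m <- matrix(c(0, 1, 1.5), nrow = 1, dimnames = list("g", c("a", "b", "c")))
  expect_equal(unname(detection_flags(m, 0)[1, ]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(detection_flags(m, 1)[1, ]), c(FALSE, FALSE, TRUE))
})

test_that("parental comparison equals the exhaustive rule oracle", {
  rpkm <- matrix(c(50, 0,    # unique to A
                   0, 50,    # unique to B
                   60, 12,   # 5-fold overexpressed in A
                   12, 60,   # 5-fold in B
                   11, 10.5, # considered, no class
                   5, 5,     # below min_rpkm
                   0.5, 15,  # unique to B
                   50, 10,   # exactly 5-fold in A (inclusive)
                   10, 10,   # not considered (strict > 10)
                   30, 29),
                 ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("g%02d", 1:10), c("A", "B")))
  res <- parental_comparison(rpkm, "A", "B")
  orc <- oracle_parental(rpkm, "A", "B", min_rpkm = 10, fold = 5,
                         detect_threshold = 1)
  expect_identical(res$unique_to_a, orc$unique_to_a)
  expect_identical(res$unique_to_b, orc$unique_to_b)
  expect_identical(res$overexpressed_a, orc$overexpressed_a)
  expect_identical(res$overexpressed_b, orc$overexpressed_b)
  expect_true("g08" %in% res$overexpressed_a)   # "at least 5 times" inclusive
  expect_false("g09" %in% c(res$unique_to_a, res$unique_to_b,
                            res$overexpressed_a, res$overexpressed_b))
  # identical parents yield empty sets
  same <- cbind(A = rpkm[, 1], B = rpkm[, 1])
  res2 <- parental_comparison(same, "A", "B")
  expect_length(res2$unique_to_a, 0)
  expect_length(res2$overexpressed_a, 0)
  expect_error(parental_comparison(rpkm, "A", "nope"), "unknown genotype")
})

test_that("pairwise candidate filter matches the all-pairs brute force", {
  producers <- sprintf("P%02d", 1:4)
  nonproducers <- sprintf("N%02d", 1:3)
  set.seed(7)
  for (rep in 1:25) {
    rpkm <- random_rpkm(20, c(producers, nonproducers))
    pools <- phenotype_pools(producers, nonproducers)
    got <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 4,
                                     pseudocount = 0.1)
    want <- oracle_pairwise_filter(rpkm, producers, nonproducers, 4, 0.1)
    expect_setequal(got$gene_id, want)
  }
})

test_that("candidate filter semantics: causal survives, uniform and leaky decoys do not", {
  producers <- sprintf("P%02d", 1:11)
  nonproducers <- sprintf("N%02d", 1:5)
  rpkm <- rbind(
    causal = c(rep(40, 11), rep(0, 5)),
    housekeeping = rep(50, 16),
    leaky = c(rep(40, 11), 40, rep(0, 4)) # detected in one non-producer
  )
  colnames(rpkm) <- c(producers, nonproducers)
  pools <- phenotype_pools(producers, nonproducers)
  out <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 4,
                                   pseudocount = 0.1)
  expect_identical(out$gene_id, "causal")
  expect_true(out$perfect_correlation)
  expect_equal(out$min_pairwise_fold, 40.1 / 0.1)
  expect_error(pairwise_candidate_filter(rpkm,
    structure(list(producers = producers, nonproducers = c("ghost")),
              class = "phenotype_pools")), "absent")
})

test_that("filter is monotone in fold threshold and safe in pseudocount for true deletions", {
  producers <- sprintf("P%02d", 1:4)
  nonproducers <- sprintf("N%02d", 1:3)
  set.seed(17)
  for (rep in 1:10) {
    rpkm <- random_rpkm(20, c(producers, nonproducers))
    pools <- phenotype_pools(producers, nonproducers)
    c2 <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 2)$gene_id
    c3 <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 3)$gene_id
    c4 <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 4)$gene_id
    expect_true(all(c3 %in% c2))
    expect_true(all(c4 %in% c3))
    # lowering the pseudocount never drops a gene whose non-producer RPKMs
    # are all zero
    zero_rows <- rownames(rpkm)[apply(rpkm[, nonproducers, drop = FALSE], 1,
                                      function(x) all(x == 0))]
    before <- intersect(
      pairwise_candidate_filter(rpkm, pools, 4, pseudocount = 0.1)$gene_id,
      zero_rows)
    after <- pairwise_candidate_filter(rpkm, pools, 4,
                                       pseudocount = 0.01)$gene_id
    expect_true(all(before %in% after))
  }
})

test_that("presence screen retains exactly the 100%-correlated candidates", {
  cand <- data.frame(gene_id = c("a", "b", "c"),
                     perfect_correlation = c(TRUE, FALSE, TRUE))
  expect_identical(presence_correlation_screen(cand)$gene_id, c("a", "c"))
  # set-comprehension oracle on a random fixture
  producers <- sprintf("P%02d", 1:5)
  nonproducers <- sprintf("N%02d", 1:4)
  set.seed(23)
  rpkm <- random_rpkm(30, c(producers, nonproducers))
  pools <- phenotype_pools(producers, nonproducers)
  out <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 2)
  flags <- detection_flags(rpkm, 1)
  want <- rownames(rpkm)[apply(flags[, producers, drop = FALSE], 1, all) &
                           !apply(flags[, nonproducers, drop = FALSE], 1, any)]
  expect_setequal(presence_correlation_screen(out)$gene_id,
                  intersect(out$gene_id, want))
})

test_that("parent-abundance ranking orders by producer-parent RPKM with id tie-break", {
  rpkm <- matrix(c(90, 0,  90, 0,  50, 0,  10, 20, 70, 0.5),
                 ncol = 2, byrow = TRUE,
                 dimnames = list(c("gB", "gA", "gC", "gD", "gE"),
                                 c("prod", "nonprod")))
  out <- rank_by_parent_abundance(rpkm, "prod", "nonprod", k = 10)
  # gD is detected in the non-producer parent, hence ineligible
  expect_identical(out$gene_id, c("gA", "gB", "gE", "gC"))
  expect_identical(rank_by_parent_abundance(rpkm, "prod", "nonprod",
                                            k = 2)$gene_id, c("gA", "gB"))
  set.seed(29)
  rpkm2 <- random_rpkm(40, c("prod", "nonprod"))
  out2 <- rank_by_parent_abundance(rpkm2, "prod", "nonprod", k = 40)
  elig <- rownames(rpkm2)[rpkm2[, "nonprod"] <= 1]
  v <- rpkm2[elig, "prod"]
  expect_identical(out2$gene_id, elig[order(-v, elig)])
})

test_that("phenotype pools reject overlap and empties", {
  expect_error(phenotype_pools(character(), "a"), "non-empty")
  expect_error(phenotype_pools(c("a", "b"), c("b", "c")), "overlap")
})
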