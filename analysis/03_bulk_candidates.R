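#!/usr/bin/env Rscript
# The discovery computation: RPKM-normalize the counts, compare the parental
# transcriptomes, pool progeny in silico by producer status, sweep the
# all-pairs fold filter over thresholds 2-4, and apply the 100%
# presence/absence-correlation screen.

library(lactomap)

em <- read_counts_tsv("results/sim/counts.tsv", "results/sim/genes.tsv",
                      "results/sim/library_sizes.tsv")
pheno <- read_phenotype_tsv("results/phenotypes.tsv")

rpkm <- compute_rpkm(em)

parental <- parental_comparison(rpkm, "parent_producer", "parent_nonproducer",
                                min_rpkm = 10, fold = 5)
print(parental)

pools <- phenotype_pools(pheno$genotype_id[pheno$status == "PRODUCER"],
                         pheno$genotype_id[pheno$status == "NONPRODUCER"])
cat(sprintf("Pools: %d producers vs %d non-producers\n",
            length(pools$producers), length(pools$nonproducers)))

for (fold in c(2, 3, 4)) {
  n <- nrow(pairwise_candidate_filter(rpkm, pools, fold_threshold = fold))
  cat(sprintf("  candidates surviving >%d-fold in every pair: %d\n", fold, n))
}

candidates <- pairwise_candidate_filter(rpkm, pools, fold_threshold = 4)
final <- presence_correlation_screen(candidates)
write.table(final, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("After the presence/absence screen: %d candidate(s)\n", nrow(final)))
print(final)

top12 <- rank_by_parent_abundance(rpkm, "parent_producer", "parent_nonproducer",
                                  k = 12)
cat("Most abundant producer-parent-specific transcripts:\n")
print(utils::head(top12, 5))
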