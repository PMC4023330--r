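#!/usr/bin/env Rscript
# Build the synthetic study population: a 16-genotype panel (2 parents + 14
# F1 progeny) segregating a dominant deletion locus, with ripe-fruit
# expression counts, a three-harvest GC/MS peak table, PCR/SSR marker panels,
# a qPCR panel and SNP pileups. Writes the same plain-text formats the rest
# of the workflow reads, so downstream steps are agnostic to the data source.

library(lactomap)

seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
pop <- simulate_population(cfg)

write_counts_tsv(pop$expression, file.path(out, "counts.tsv"),
                 file.path(out, "genes.tsv"), file.path(out, "library_sizes.tsv"))
write_peaks_csv(pop$volatiles, file.path(out, "peaks.csv"))
write_marker_tsv(pop$markers, file.path(out, "markers.tsv"))
write_ssr_tsv(pop$ssr, file.path(out, "ssr.tsv"))
write_qpcr_csv(pop$qpcr, file.path(out, "qpcr.csv"))
write_pileup_tsv(pop$pileups, file.path(out, "pileup.tsv"))

n_carrier <- sum(pop$genotypes$carrier)
cat(sprintf("Simulated %d genotypes (%d carriers / %d non-carriers), %d genes, seed %d\n",
            nrow(pop$genotypes), n_carrier,
            nrow(pop$genotypes) - n_carrier, nrow(pop$expression$counts), seed))
cat(sprintf("Causal deletion gene: %s\n", causal_gene_id(cfg)))
cat(sprintf("Tables written under %s/\n", out))
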