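#!/usr/bin/env Rscript
# SNP filtering: apply the per-genotype depth (>= 10) and non-reference
# fraction (>= 0.95) criteria to the pileup summaries, keep sites supported
# by at least two genotypes, and emit a minimal VCF.

library(lactomap)

sites <- read_pileup_tsv("results/sim/pileup.tsv")
calls <- filter_snps(sites, min_nonref_frac = 0.95, min_depth = 10,
                     min_genotypes = 2)
n_sites <- length(unique(paste(sites$chrom, sites$pos)))
cat(sprintf("%d of %d sites pass the SNP criteria\n", nrow(calls), n_sites))

ids <- sort(unique(sites$genotype_id))
write_vcf(calls, ids, "results/snps.vcf")
cat("VCF written to results/snps.vcf\n")
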