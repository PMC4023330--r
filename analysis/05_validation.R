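#!/usr/bin/env Rscript
# Validation statistics: segregation chi-square, PCR-marker concordance with
# its cosegregation test, SSR allele association, and comparative-CT fold
# changes (the per-genotype panel and a ripening stage pair).

library(lactomap)

pheno <- read_phenotype_tsv("results/phenotypes.tsv")
markers <- read_marker_tsv("results/sim/markers.tsv")
ssr <- read_ssr_tsv("results/sim/ssr.tsv")
qpcr <- read_qpcr_csv("results/sim/qpcr.csv")

progeny <- pheno[!pheno$genotype_id %in%
                   c("parent_producer", "parent_nonproducer"), ]
seg <- chi_square_ratio(c(producer = sum(progeny$status == "PRODUCER"),
                          nonproducer = sum(progeny$status == "NONPRODUCER")),
                        c(1, 1))
cat("Segregation of the volatile among progeny:\n")
print(seg)

conc <- marker_concordance(markers, pheno)
print(conc)

assoc <- ssr_allele_association(ssr, pheno)
cat("SSR allele association (unadjusted; single-locus confirmatory screen):\n")
print(assoc)

cat("Per-genotype relative target expression vs the producer parent:\n")
for (id in unique(qpcr$condition)) {
  if (id == "parent_producer") next
  fc <- ddct_fold_change(qpcr, id, "parent_producer")
  cat(sprintf("  %-20s fold %6.3g%s\n", id, fc$fold,
              if (fc$no_amplification) " (no amplification)" else ""))
}

# ripening induction in a carrier background
stage <- simulate_qpcr(data.frame(id = "parent_producer", carrier = TRUE),
                       sim_config(seed = 1), design = "stage_pair")
fc <- ddct_fold_change(stage, "ripe", "blushing")
cat(sprintf("Ripening induction (ripe vs blushing): %.3g-fold (+/- %.2g cycles)\n",
            fc$fold, fc$sd_ct))

summary <- data.frame(
  statistic = c("segregation_chi_square", "segregation_p",
                "marker_concordance", "cosegregation_p"),
  value = c(seg$chi_square, seg$p_value, conc$concordance, conc$p_value)
)
write.table(summary, "results/validation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
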