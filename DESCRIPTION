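Package: lactomap
Title: Presence/Absence Bulked-Segregant Transcriptomics for a Fruit
    Volatile Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico bulked-segregant workflow for mapping a
    qualitative fruit-volatile phenotype (gamma-decalactone presence or
    absence) to a candidate gene in a segregating octoploid strawberry
    population. Provides GC/MS volatile phenotyping from internal-standard
    normalized peak tables (producer calls, five-class seasonal trends,
    standard-curve concentration estimates), RPKM quantification with
    parental comparison and an all-pairs fold-change plus
    presence/absence-correlation candidate filter, read-depth and
    allele-fraction SNP filtering with minimal VCF output, validation
    statistics (comparative-CT fold change, chi-square segregation tests,
    PCR-marker concordance, SSR allele association), and a seeded
    simulator of segregating populations carrying a dominant deletion
    locus so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics
Config/testthat/edition: 3
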