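# Readers and writers for the pipeline's plain-text table formats.
# Dialect: TSV with a mandatory header row, '.' for missing numeric cells,
# UTF-8; peak tables are CSV. Readers validate schemas and reject duplicate
# ids so downstream joins are unambiguous.

read_table_checked <- function(path, required, sep = "\t", what = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = ".", quote = "\"",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s (header line 1)", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_table_checked <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-level count matrix with lengths and library sizes
#'
#' @param counts_path TSV with a `gene_id` column followed by one column
#'   per genotype.
#' @param genes_path TSV with `gene_id`, `length_bp`.
#' @param library_path Optional TSV with `genotype_id`, `library_size`;
#'   when `NULL`, library sizes are the count column sums.
#' @return An [expression_matrix()].
#' @export
read_counts_tsv <- function(counts_path, genes_path, library_path = NULL) {
  counts_df <- read_table_checked(counts_path, "gene_id")
  if (ncol(counts_df) < 2L) {
    stop("counts table has no genotype columns", call. = FALSE)
  }
  if (anyDuplicated(counts_df$gene_id)) {
    stop("counts table: duplicate gene_id ",
         counts_df$gene_id[duplicated(counts_df$gene_id)][1L], call. = FALSE)
  }
  if (anyDuplicated(names(counts_df))) {
    stop("counts table: duplicate genotype column ",
         names(counts_df)[duplicated(names(counts_df))][1L], call. = FALSE)
  }
  m <- as.matrix(counts_df[, -1L, drop = FALSE])
  if (any(is.na(m))) {
    i <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("counts table: missing count for gene %s, genotype %s",
                 counts_df$gene_id[i[1L]], colnames(m)[i[2L]]), call. = FALSE)
  }
  rownames(m) <- counts_df$gene_id
  genes <- read_table_checked(genes_path, c("gene_id", "length_bp"))
  lens <- stats::setNames(genes$length_bp, genes$gene_id)
  libs <- NULL
  if (!is.null(library_path)) {
    lib_df <- read_table_checked(library_path, c("genotype_id", "library_size"))
    libs <- stats::setNames(lib_df$library_size, lib_df$genotype_id)
  }
  expression_matrix(m, lens, libs)
}

#' Write a count matrix as counts + genes + library-size TSVs
#'
#' @param em An [expression_matrix()].
#' @param counts_path,genes_path,library_path Output paths.
#' @return Invisibly, the counts path.
#' @export
write_counts_tsv <- function(em, counts_path, genes_path, library_path) {
  stopifnot(inherits(em, "expression_matrix"))
  write_table_checked(
    data.frame(gene_id = rownames(em$counts), em$counts, check.names = FALSE),
    counts_path)
  write_table_checked(
    data.frame(gene_id = names(em$gene_lengths), length_bp = em$gene_lengths),
    genes_path)
  write_table_checked(
    data.frame(genotype_id = names(em$library_sizes),
               library_size = em$library_sizes),
    library_path)
  invisible(counts_path)
}

#' Read a GC/MS peak table (CSV)
#'
#' Columns: `genotype_id`, `harvest_id`, `environment`, `replicate`,
#' `gd_area`, `is_area`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_peaks_csv <- function(path) {
  read_table_checked(path, c("genotype_id", "harvest_id", "environment",
                             "replicate", "gd_area", "is_area"), sep = ",")
}

#' @rdname read_peaks_csv
#' @param peaks Peak table data frame.
#' @export
write_peaks_csv <- function(peaks, path) {
  write_table_checked(peaks, path, sep = ",")
}

#' Read / write the phenotype table (TSV)
#'
#' Columns: `genotype_id`, `status`, `trend_class`, `n_harvests`.
#' @param path TSV path.
#' @return Data frame.
#' @export
read_phenotype_tsv <- function(path) {
  df <- read_table_checked(path, c("genotype_id", "status"))
  if (anyDuplicated(df$genotype_id)) {
    stop("phenotype table: duplicate genotype_id", call. = FALSE)
  }
  df
}

#' @rdname read_phenotype_tsv
#' @param phenotypes Phenotype data frame.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  write_table_checked(phenotypes, path)
}

#' Read the PCR marker table (TSV)
#'
#' Columns: `genotype_id`, `amplicon` (0/1), `control` (0/1).
#' @param path TSV path.
#' @return Data frame with logical `amplicon_present`, `control_present`.
#' @export
read_marker_tsv <- function(path) {
  df <- read_table_checked(path, c("genotype_id", "amplicon", "control"))
  data.frame(genotype_id = df$genotype_id,
             amplicon_present = df$amplicon == 1,
             control_present = df$control == 1,
             stringsAsFactors = FALSE)
}

#' @rdname read_marker_tsv
#' @param markers Marker data frame (logical columns as from
#'   [simulate_marker_panel()]).
#' @export
write_marker_tsv <- function(markers, path) {
  write_table_checked(
    data.frame(genotype_id = markers$genotype_id,
               amplicon = as.integer(markers$amplicon_present),
               control = as.integer(markers$control_present)),
    path)
}

#' Read / write the SSR allele table (TSV)
#'
#' Columns: `genotype_id`, `alleles` (comma-separated fragment sizes).
#' @param path TSV path.
#' @return Data frame.
#' @export
read_ssr_tsv <- function(path) {
  read_table_checked(path, c("genotype_id", "alleles"))
}

#' @rdname read_ssr_tsv
#' @param ssr SSR data frame.
#' @export
write_ssr_tsv <- function(ssr, path) {
  write_table_checked(ssr, path)
}

#' Read / write the long-format pileup table (TSV)
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `genotype_id`, `depth`,
#' `nonref_count`.
#' @param path TSV path.
#' @return Data frame.
#' @export
read_pileup_tsv <- function(path) {
  read_table_checked(path, c("chrom", "pos", "ref", "alt", "genotype_id",
                             "depth", "nonref_count"))
}

#' @rdname read_pileup_tsv
#' @param sites Pileup data frame.
#' @export
write_pileup_tsv <- function(sites, path) {
  write_table_checked(sites, path)
}

#' Read / write the qPCR table (CSV)
#'
#' Columns: `condition`, `gene`, `replicate`, `ct` (missing = no
#' amplification, written as '.').
#' @param path CSV path.
#' @return Data frame.
#' @export
read_qpcr_csv <- function(path) {
  read_table_checked(path, c("condition", "gene", "replicate", "ct"),
                     sep = ",")
}

#' @rdname read_qpcr_csv
#' @param qpcr qPCR data frame.
#' @export
write_qpcr_csv <- function(qpcr, path) {
  write_table_checked(qpcr, path, sep = ",")
}
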