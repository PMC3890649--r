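# Readers and writers for the package's plain-text formats.  User-facing
# coordinates in every file are TSS-anchored (1-based, no zero, promoter
# negative); internal computation is plain array offsets.

file_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("polyhap"))
  h <- paste0("#polyhap ", v)
  if (!is.null(seed)) h <- paste0(h, "; seed=", seed)
  h
}

write_tsv_with_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_header <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings with the package's conventions: records
#' are uppercased on read (with a message when lowercase was present),
#' duplicate ids are an error, and writing wraps sequences at 60 columns so
#' a write/read cycle is byte-stable for normalized records.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  if (anyDuplicated(ids)) stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- as.character(ss)
  if (any(grepl("[a-z]", seqs))) {
    message("lowercase bases uppercased on read")
    seqs <- toupper(seqs)
  }
  if (any(grepl("[^ACGTRYSWKMBDHVN]", seqs)))
    stop("non-nucleotide characters in FASTA sequence")
  names(seqs) <- ids
  seqs
}

#' @param sequences Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(toupper(sequences)), path, width = 60L)
  invisible(path)
}

#' Read and write variant tables (VCF-like TSV)
#'
#' Columns: `CHROM` (gene id), `POS` (TSS-anchored), `REF`, `ALT`, `KIND`,
#' `LEN`, `CARRIERS` (comma-separated).  Files begin with a `#` comment
#' header carrying the tool version and seed.
#'
#' @param variants Variant data frame (see [diff_haplotype()]).
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @return `read_variants_tsv()` returns a variant data frame.
#' @export
write_variants_tsv <- function(variants, path, seed = NULL) {
  df <- data.frame(CHROM = variants$gene_id, POS = variants$position,
                   REF = variants$ref, ALT = variants$alt,
                   KIND = variants$kind, LEN = variants$length,
                   CARRIERS = variants$carriers)
  write_tsv_with_header(df, path, seed)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  df <- read_tsv_skip_header(path, colClasses = c(
    CHROM = "character", POS = "integer", REF = "character",
    ALT = "character", KIND = "character", LEN = "integer",
    CARRIERS = "character"))
  df$CARRIERS[is.na(df$CARRIERS)] <- ""
  data.frame(gene_id = df$CHROM, position = df$POS, kind = df$KIND,
             ref = df$REF, alt = df$ALT, length = df$LEN,
             carriers = df$CARRIERS)
}

#' Read and write the aligned-read TSV dialect
#'
#' One row per pre-placed read: `read_id`, `start` (TSS-anchored coordinate
#' of the first base), `strand`, `seq`, `qual` (phred+33 string),
#' `unique_flag` (0/1).
#'
#' @param reads Read data frame (see [simulate_reads()]).
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_reads_tsv <- function(reads, path, seed = NULL) {
  cols <- c("read_id", "start", "strand", "seq", "qual", "unique_flag")
  write_tsv_with_header(reads[, cols], path, seed)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  read_tsv_skip_header(path, colClasses = c(
    read_id = "character", start = "integer", strand = "character",
    seq = "character", qual = "character", unique_flag = "integer"))
}

#' Read and write region annotations (GFF-like TSV)
#'
#' Columns: `feature`, `start`, `end` (TSS-anchored, inclusive), `strand`
#' (always `+`), `size`.
#'
#' @param regions Region table (see [annotate_regions()]).
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_regions_tsv <- function(regions, path, seed = NULL) {
  df <- data.frame(feature = regions$label, start = regions$start,
                   end = regions$end, strand = "+", size = regions$size)
  write_tsv_with_header(df, path, seed)
}

#' @rdname write_regions_tsv
#' @export
read_regions_tsv <- function(path) {
  df <- read_tsv_skip_header(path)
  data.frame(label = df$feature, start = df$start, end = df$end,
             size = df$size)
}

#' Read a motif library from TSV
#'
#' Expects columns `motif_id`, `pattern` and optionally `function_note`.
#'
#' @param path File path.
#' @return A [motif_library()].
#' @export
read_motif_library <- function(path) {
  df <- read_tsv_skip_header(path)
  motif_library(df$motif_id, df$pattern,
                if ("function_note" %in% names(df)) df$function_note else "")
}

#' Read a per-library FPKM table from TSV
#'
#' Expects columns `library_id`, `gene_id`, `fpkm`.
#'
#' @param path File path.
#' @return Data frame suitable for [compare_expression()].
#' @export
read_fpkm_tsv <- function(path) {
  df <- read_tsv_skip_header(path)
  if (!all(c("library_id", "gene_id", "fpkm") %in% names(df)))
    stop("FPKM table needs columns library_id, gene_id, fpkm")
  df
}

#' Write a region variant summary in report layout
#'
#' Emits the feature-wise summary in the conventional column order (Region,
#' Nucleotide position, Size, Number of indels, Number of SNPs, SNP
#' frequency), rendering an undefined SNP frequency as `-`.
#'
#' @param summary Output of [summarize_regions()].
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_region_summary_tsv <- function(summary, path, seed = NULL) {
  df <- data.frame(
    Region = summary$label,
    `Nucleotide position` = paste(summary$start, "to", summary$end),
    Size = summary$size,
    `Number of indels` = summary$n_indels,
    `Number of SNPs` = summary$n_snps,
    `SNP frequency (nucleotides/SNP)` = ifelse(
      is.na(summary$nts_per_snp), "-",
      formatC(summary$nts_per_snp, format = "f", digits = 1)),
    check.names = FALSE)
  write_tsv_with_header(df, path, seed)
}
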