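# Feature-wise SNP/indel density accounting (nucleotides per SNP) and the
# per-library expression comparison.

# Half-away-from-zero rounding (base round() rounds half to even, which
# would turn 52.5 into 52).  A small epsilon guards quotients of integers
# against representation error.
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Per-region SNP and indel counts and SNP density
#'
#' Partitions a variant table over a region annotation and computes, per
#' region, the indel count, SNP count and the conservation statistic
#' nucleotides-per-SNP (region size divided by SNP count, rounded to one
#' decimal, half away from zero; undefined — `NA` — when a region holds no
#' SNPs).  An indel is assigned to the region of its first affected
#' reference base.
#'
#' @param variants Variant data frame (see [diff_haplotype()]).
#' @param regions Region table (see [annotate_regions()]).
#' @return Data frame with columns `label`, `start`, `end`, `size`,
#'   `n_indels`, `n_snps`, `nts_per_snp`.
#' @export
summarize_regions <- function(variants, regions) {
  n_snps <- integer(nrow(regions)); n_indels <- integer(nrow(regions))
  if (nrow(variants)) {
    idx <- vapply(variants$position, function(p) {
      w <- which(regions$start <= p & p <= regions$end)
      if (length(w) != 1L)
        stop("variant at position ", p, " falls outside the region annotation")
      w
    }, integer(1))
    for (i in seq_along(idx)) {
      if (variants$kind[i] == "SNP") n_snps[idx[i]] <- n_snps[idx[i]] + 1L
      else n_indels[idx[i]] <- n_indels[idx[i]] + 1L
    }
  }
  out <- regions[, c("label", "start", "end", "size")]
  out$n_indels <- n_indels
  out$n_snps <- n_snps
  out$nts_per_snp <- ifelse(n_snps > 0L,
                            round_half_away(out$size / n_snps, 1L), NA_real_)
  rownames(out) <- NULL
  out
}

#' Aggregate SNP density over a set of regions
#'
#' Pooled nucleotides-per-SNP over the selected regions: the summed sizes
#' divided by the summed SNP counts, rounded to the nearest integer (half
#' away from zero).  Undefined (`NA`) when the selected regions hold no
#' SNPs.
#'
#' @param summaries Output of [summarize_regions()].
#' @param labels Region labels to pool (must select at least one region).
#' @return A single number (nucleotides per SNP) or `NA`.
#' @export
#' @examples
#' s <- data.frame(label = c("exon_1", "exon_2"), start = 1, end = 1,
#'                 size = c(82, 185), n_indels = 0, n_snps = c(2, 2),
#'                 nts_per_snp = c(41, 92.5))
#' aggregate_frequency(s, c("exon_1", "exon_2"))  # 67
aggregate_frequency <- function(summaries, labels) {
  unknown <- setdiff(labels, summaries$label)
  if (length(unknown)) stop("unknown region label: ", unknown[1L])
  sel <- summaries[summaries$label %in% labels, ]
  if (nrow(sel) == 0L) stop("labels must select at least one region")
  tot_snps <- sum(sel$n_snps)
  if (tot_snps == 0L) return(NA_real_)
  round_half_away(sum(sel$size) / tot_snps, 0L)
}

#' Compare expression of two genes across libraries
#'
#' Per-library strict comparison of FPKM values: counts in how many
#' libraries each gene is the more highly expressed one (zero FPKM
#' participates as the value 0).
#'
#' @param records Data frame with columns `library_id`, `gene_id`, `fpkm`.
#' @param gene_a,gene_b Gene labels; both must be present in every library.
#' @return A list with `n_a_higher`, `n_b_higher`, `n_tied`, `n_libraries`,
#'   and a per-library data frame `libraries`.
#' @export
compare_expression <- function(records, gene_a, gene_b) {
  if (any(records$fpkm < 0)) stop("fpkm values must be >= 0")
  libs <- unique(records$library_id)
  get1 <- function(lib, gene) {
    v <- records$fpkm[records$library_id == lib & records$gene_id == gene]
    if (length(v) != 1L)
      stop("library '", lib, "' lacks a unique record for gene '", gene, "'")
    v
  }
  a <- vapply(libs, get1, numeric(1), gene = gene_a)
  b <- vapply(libs, get1, numeric(1), gene = gene_b)
  list(n_a_higher = sum(a > b), n_b_higher = sum(b > a), n_tied = sum(a == b),
       n_libraries = length(libs),
       libraries = data.frame(library_id = libs, fpkm_a = a, fpkm_b = b,
                              higher = ifelse(a > b, gene_a,
                                              ifelse(b > a, gene_b, "tie")),
                              row.names = NULL))
}
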