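# Haplotype-versus-reference variant discovery via affine-gap global
# alignment, and merging of per-genotype variant tables.

#' Alignment scoring parameters
#'
#' Scoring for pairwise global alignment with affine gaps: a gap of length L
#' costs `gap_open + L * gap_extend`.  The defaults (match 2, mismatch -3,
#' gap open 5, gap extend 2) make gaps expensive enough that well-separated
#' planted variants are recovered exactly.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening penalty (>= 0).
#' @param gap_extend Per-base gap extension penalty (>= 0).
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                              gap_extend = 2) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (match <= 0 || mismatch >= 0) stop("need match > 0 and mismatch < 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_scoring")
}

#' Global pairwise alignment with affine gap penalties
#'
#' Optimal-score global (end-to-end) alignment of two nucleotide sequences.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param scoring An [alignment_scoring()].
#' @return A list with elements `score`, `a_aln`, `b_aln` (gapped strings of
#'   equal length), of class `pairwise_alignment`.
#' @export
#' @examples
#' align_global("ACGT", "AGT")
align_global <- function(a, b, scoring = alignment_scoring()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  structure(list(score = Biostrings::score(pa),
                 a_aln = as.character(Biostrings::alignedPattern(pa)),
                 b_aln = as.character(Biostrings::alignedSubject(pa))),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "\n")
  cat(x$a_aln, "\n", x$b_aln, "\n", sep = "")
  invisible(x)
}

#' Variants distinguishing a haplotype from its reference
#'
#' Globally aligns a haplotype against the reference and converts the
#' alignment into a variant table: each mismatch column becomes one SNP and
#' each maximal contiguous gap run becomes one indel (so a 7 nt deletion is
#' one event of length 7).  Positions are TSS-anchored coordinates of the
#' reference; an insertion is anchored at the reference base before which
#' the inserted bases sit.
#'
#' @param ref Reference nucleotide string.
#' @param hap Haplotype nucleotide string.
#' @param scoring An [alignment_scoring()].
#' @param tss_index Array offset of position +1 in `ref` (default 1 gives
#'   plain 1-based coordinates).
#' @param gene_id Gene label recorded in the table.
#' @param carrier Optional haplotype/genotype id recorded in `carriers`.
#' @return Variant data frame with columns `gene_id`, `position`, `kind`
#'   (`"SNP"`/`"indel"`), `ref`, `alt` (`"-"` marks the empty side of an
#'   indel), `length`, `carriers`.
#' @export
diff_haplotype <- function(ref, hap, scoring = alignment_scoring(),
                           tss_index = 1L, gene_id = "gene",
                           carrier = NULL) {
  aln <- align_global(ref, hap, scoring)
  ra <- strsplit(aln$a_aln, "")[[1L]]
  ha <- strsplit(aln$b_aln, "")[[1L]]
  n <- length(ra)
  ref_off <- cumsum(ra != "-")          # reference offset at each column
  state <- ifelse(ra == "-", "ins", ifelse(ha == "-", "del",
                  ifelse(ra == ha, "eq", "snp")))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  vars <- list()
  for (k in seq_along(runs$values)) {
    st <- runs$values[k]
    if (st == "eq") next
    i <- starts[k]; j <- ends[k]
    if (st == "snp") {
      for (c0 in i:j) {
        vars[[length(vars) + 1L]] <- data.frame(
          position = ref_off[c0], kind = "SNP", ref = ra[c0], alt = ha[c0],
          length = 1L)
      }
    } else if (st == "del") {
      vars[[length(vars) + 1L]] <- data.frame(
        position = ref_off[i], kind = "indel",
        ref = paste(ra[i:j], collapse = ""), alt = "-", length = j - i + 1L)
    } else { # insertion relative to the reference
      anchor <- if (j < n) ref_off[j] + 1L else ref_off[i]
      vars[[length(vars) + 1L]] <- data.frame(
        position = anchor, kind = "indel", ref = "-",
        alt = paste(ha[i:j], collapse = ""), length = j - i + 1L)
    }
  }
  out <- if (length(vars)) do.call(rbind, vars) else
    data.frame(position = integer(0), kind = character(0), ref = character(0),
               alt = character(0), length = integer(0))
  out$position <- offset_to_pos(pmax(out$position, 1L), tss_index)
  out$gene_id <- rep(gene_id, nrow(out))
  out$carriers <- rep(if (is.null(carrier)) "" else carrier, nrow(out))
  out <- out[, c("gene_id", "position", "kind", "ref", "alt", "length",
                 "carriers")]
  out[order(pos_to_offset(out$position, tss_index)), , drop = FALSE]
}

#' Merge per-genotype variant tables
#'
#' Variants identical in (position, kind, ref, alt) are merged into one
#' event with the union of their carriers; the merged table is sorted by
#' reference position.  Two SNPs at the same position must agree on the
#' reference base.
#'
#' @param tables A list of variant data frames sharing one reference
#'   coordinate system (see [diff_haplotype()]).
#' @return A single merged variant data frame.
#' @export
merge_variant_tables <- function(tables) {
  tab <- do.call(rbind, tables)
  if (is.null(tab) || nrow(tab) == 0L) return(tab)
  snp <- tab[tab$kind == "SNP", ]
  if (nrow(snp)) {
    refs <- tapply(snp$ref, snp$position, function(x) length(unique(x)))
    if (any(refs > 1L))
      stop("conflicting reference allele at position ",
           names(refs)[refs > 1L][1L])
  }
  key <- paste(tab$position, tab$kind, tab$ref, tab$alt, sep = "\r")
  merged <- lapply(split(tab, key), function(grp) {
    carr <- sort(unique(unlist(strsplit(grp$carriers, ","))))
    carr <- carr[carr != ""]
    out <- grp[1L, , drop = FALSE]
    out$carriers <- paste(carr, collapse = ",")
    out
  })
  out <- do.call(rbind, merged)
  # sort by position honouring the no-zero convention (numeric order works)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
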