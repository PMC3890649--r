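# Pileup construction from pre-placed reads and SNP calling with
# quality / read-support / unique-mapping filters.

#' Caller thresholds for pileup SNP calling
#'
#' The defaults encode a conservative filter for polyploid short-read data:
#' only uniquely mapped reads are used, a base observation passes only if
#' its quality is strictly above phred 15, and an alternative base is called
#' only when supported by at least three passing reads.  No minimum
#' alternative-allele fraction is imposed by default, since a simplex allele
#' in a tetraploid is expected in only ~25% of reads.
#'
#' @param min_base_quality Phred threshold; observations must be strictly
#'   above it.
#' @param min_alt_reads Minimum number of passing reads supporting the
#'   alternative base.
#' @param unique_only Use only reads flagged as uniquely mapped.
#' @param min_alt_fraction Minimum fraction of passing reads carrying the
#'   alternative base.
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(min_base_quality = 15L, min_alt_reads = 3L,
                          unique_only = TRUE, min_alt_fraction = 0) {
  if (min_base_quality < 0 || min_alt_reads < 0 || min_alt_fraction < 0)
    stop("thresholds must be non-negative")
  structure(list(min_base_quality = min_base_quality,
                 min_alt_reads = min_alt_reads, unique_only = unique_only,
                 min_alt_fraction = min_alt_fraction),
            class = "caller_config")
}

#' Build a per-position pileup from pre-placed reads
#'
#' Stacks read observations position by position.  Reads must be SNP-only
#' relative to the reference (the read dialect carries no gaps), placed by
#' the TSS-anchored coordinate of their first base.
#'
#' @param reads Read data frame as produced by [simulate_reads()] or
#'   [read_reads_tsv()] (columns `read_id`, `start`, `seq`, `qual`,
#'   `unique_flag`).
#' @param model The reference [gene_model()].
#' @return A data frame of class `pileup_table` with one row per read
#'   observation: `position` (TSS-anchored), `ref_base`, `base`, `qual`
#'   (integer phred), `unique_flag`, `read_id`.
#' @export
pileup_from_reads <- function(reads, model) {
  stopifnot(inherits(model, "gene_model"))
  L <- nchar(model$sequence)
  if (nrow(reads) == 0L)
    return(structure(data.frame(position = integer(0), ref_base = character(0),
                                base = character(0), qual = integer(0),
                                unique_flag = integer(0), read_id = character(0)),
                     class = c("pileup_table", "data.frame")))
  rl <- nchar(reads$seq)
  off <- pos_to_offset(reads$start, model$tss_index, L)
  if (any(off + rl - 1L > L))
    stop("read ", reads$read_id[which(off + rl - 1L > L)[1L]],
         " extends past the reference end")
  refch <- strsplit(model$sequence, "")[[1L]]
  offsets <- unlist(lapply(seq_len(nrow(reads)),
                           function(i) off[i]:(off[i] + rl[i] - 1L)))
  obs <- data.frame(
    position = offset_to_pos(offsets, model$tss_index),
    ref_base = refch[offsets],
    base = unlist(strsplit(reads$seq, "")),
    qual = unlist(lapply(reads$qual, function(q) utf8ToInt(q) - 33L)),
    unique_flag = rep(reads$unique_flag, rl),
    read_id = rep(reads$read_id, rl))
  class(obs) <- c("pileup_table", "data.frame")
  obs
}

#' Call SNPs from a pileup with quality and support filters
#'
#' An observation passes if (when `unique_only`) its read is uniquely mapped
#' and its base quality is strictly above `min_base_quality`.  An
#' alternative base is called at a position when its passing support reaches
#' `min_alt_reads` and its fraction of all passing observations at that
#' position reaches `min_alt_fraction`.  One call is emitted per
#' (position, alternative base).
#'
#' @param pileup A `pileup_table` from [pileup_from_reads()].
#' @param cfg A [caller_config()].
#' @return Data frame with columns `position`, `ref`, `alt`,
#'   `supporting_reads`, `total_passing_reads`.
#' @export
call_snps_polysnp <- function(pileup, cfg = caller_config()) {
  empty <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0), supporting_reads = integer(0),
                      total_passing_reads = integer(0))
  pass <- pileup$qual > cfg$min_base_quality
  if (cfg$unique_only) pass <- pass & pileup$unique_flag == 1L
  p <- pileup[pass, , drop = FALSE]
  if (nrow(p) == 0L) return(empty)
  tot <- tapply(rep(1L, nrow(p)), p$position, sum)
  alt <- p[p$base != p$ref_base, , drop = FALSE]
  if (nrow(alt) == 0L) return(empty)
  agg <- stats::aggregate(list(supporting_reads = rep(1L, nrow(alt))),
                          by = list(position = alt$position, ref = alt$ref_base,
                                    alt = alt$base), FUN = sum)
  agg$total_passing_reads <- as.integer(tot[as.character(agg$position)])
  keep <- agg$supporting_reads >= cfg$min_alt_reads &
    agg$supporting_reads / agg$total_passing_reads >= cfg$min_alt_fraction
  out <- agg[keep, c("position", "ref", "alt", "supporting_reads",
                     "total_passing_reads"), drop = FALSE]
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
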