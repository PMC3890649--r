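# Promoter analysis: degenerate IUPAC motif scanning on both strands, TSS
# prediction by the pyrimidine-purine (YR) dimer rule, core promoter
# element search, and motif-disruption detection against variant tables.

#' Define a promoter motif library
#'
#' @param motif_id Character vector of motif identifiers.
#' @param pattern Character vector of IUPAC degenerate patterns (uppercase
#'   A C G T R Y S W K M B D H V N).
#' @param function_note Optional free-text annotation per motif.
#' @return Data frame of class `motif_library`.
#' @export
motif_library <- function(motif_id, pattern, function_note = "") {
  pattern <- toupper(pattern)
  if (any(nchar(pattern) == 0L)) stop("motif patterns must be non-empty")
  bad <- regmatches(pattern, regexpr("[^ACGTRYSWKMBDHVN]", pattern))
  if (length(bad) && any(nzchar(bad)))
    stop("invalid IUPAC character: ", bad[nzchar(bad)][1L])
  structure(data.frame(motif_id = motif_id, pattern = pattern,
                       function_note = rep_len(function_note,
                                               length(motif_id))),
            class = c("motif_library", "data.frame"))
}

#' Scan a sequence for degenerate motifs on both strands
#'
#' Exact degenerate matching (IUPAC letters match their base sets; no
#' mismatches, no scoring matrix).  Every occurrence on either strand is
#' reported, including overlapping ones.  Coordinates are TSS-anchored and
#' given in the motif's own 5'->3' orientation: a plus-strand hit has
#' `start < end`, while a minus-strand hit is reported with `start` at the
#' downstream-most coordinate, so `start > end`.  The normalized span
#' (`span_lo`, `span_hi`) is also returned for interval logic.
#'
#' @param x Sequence to scan: either a nucleotide string or a
#'   [gene_model()], in which case the promoter region is scanned.
#' @param library A [motif_library()] (or data frame with `motif_id`,
#'   `pattern`).
#' @param first_pos TSS-anchored coordinate of the first base of `x`
#'   (ignored when `x` is a gene model).
#' @return Data frame with columns `motif_id`, `start`, `end`, `strand`,
#'   `matched`, `span_lo`, `span_hi`.
#' @export
#' @examples
#' lib <- motif_library("MYB1AT", "WAACCA")
#' scan_motifs("AAACCATAACCA", lib, first_pos = -12)
scan_motifs <- function(x, library, first_pos = 1L) {
  if (inherits(x, "gene_model")) {
    prom <- x$regions[x$regions$label == "promoter", ]
    if (nrow(prom) != 1L) stop("model has no single promoter region")
    first_pos <- prom$start
    x <- model_subseq(x, prom$start, prom$end)
  }
  seq <- toupper(x)
  pc <- tss_coords(first_pos, nchar(seq))
  subj <- Biostrings::DNAString(seq)
  hits <- list()
  for (i in seq_len(nrow(library))) {
    pat <- toupper(library$pattern[i])
    if (grepl("[^ACGTRYSWKMBDHVN]", pat))
      stop("invalid IUPAC character in pattern ", pat)
    plus <- Biostrings::matchPattern(pat, subj, fixed = "subject")
    for (k in seq_along(plus)) {
      s <- Biostrings::start(plus)[k]; e <- Biostrings::end(plus)[k]
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = library$motif_id[i], start = pc[s], end = pc[e],
        strand = "+", matched = as.character(plus[[k]]),
        span_lo = pc[s], span_hi = pc[e])
    }
    minus <- Biostrings::matchPattern(revcomp(pat), subj, fixed = "subject")
    for (k in seq_along(minus)) {
      s <- Biostrings::start(minus)[k]; e <- Biostrings::end(minus)[k]
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = library$motif_id[i], start = pc[e], end = pc[s],
        strand = "-", matched = revcomp(as.character(minus[[k]])),
        span_lo = pc[s], span_hi = pc[e])
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), matched = character(0),
               span_lo = integer(0), span_hi = integer(0))
  rownames(out) <- NULL
  out
}

#' Predict transcription start site candidates by the YR dimer rule
#'
#' In plants the TSS tends to fall on a purine (+1) immediately preceded by
#' a pyrimidine (-1).  Every such pyrimidine-purine dimer within the search
#' window upstream of the ATG is a candidate; candidates are ranked first by
#' the presence of a TATA element (a `TATAWA` match) ending within
#' `tata_offset_range` nucleotides upstream of the candidate +1, then by
#' proximity to the ATG.
#'
#' @param seq Nucleotide string containing the promoter and the start
#'   codon.
#' @param atg_offset 1-based array offset of the A of the start codon in
#'   `seq`.
#' @param window Search window size in nt upstream of the ATG.
#' @param tata_offset_range Admissible distance (nt) from a TATA element end
#'   to the candidate +1.
#' @return Data frame of ranked candidates: `tss_offset` (array offset of
#'   +1), `upstream_of_atg` (nt between +1 and the ATG), `dimer`,
#'   `has_tata`, `tata_end_offset`, `rank`.  Empty when the window holds no
#'   YR dimer.
#' @export
predict_tss <- function(seq, atg_offset, window = 100L,
                        tata_offset_range = c(25L, 35L)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (atg_offset < 2L || atg_offset > n) stop("ATG offset outside sequence")
  ch <- strsplit(seq, "")[[1L]]
  lo <- max(2L, atg_offset - window)
  cand <- (lo:(atg_offset - 1L))
  cand <- cand[ch[cand - 1L] %in% c("C", "T") & ch[cand] %in% c("A", "G")]
  if (length(cand) == 0L)
    return(data.frame(tss_offset = integer(0), upstream_of_atg = integer(0),
                      dimer = character(0), has_tata = logical(0),
                      tata_end_offset = integer(0), rank = integer(0)))
  tata <- Biostrings::matchPattern("TATAWA", Biostrings::DNAString(seq),
                                   fixed = "subject")
  tata_ends <- Biostrings::end(tata)
  info <- lapply(cand, function(t) {
    d <- t - tata_ends
    ok <- d >= tata_offset_range[1L] & d <= tata_offset_range[2L]
    data.frame(tss_offset = t, upstream_of_atg = atg_offset - t,
               dimer = paste0(ch[t - 1L], ch[t]), has_tata = any(ok),
               tata_end_offset = if (any(ok)) max(tata_ends[ok]) else
                 NA_integer_)
  })
  out <- do.call(rbind, info)
  out <- out[order(!out$has_tata, out$upstream_of_atg), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Locate core promoter elements upstream of a TSS
#'
#' Searches fixed windows upstream of the TSS for the three classic core
#' elements: the TATA-box (best `TATAWA` match in -45..-20; the
#' downstream-most exact match wins), the pyrimidine patch (longest run of
#' at least 5 pyrimidines in -60..-10; ties resolved downstream), and the
#' CAAT-box (exact `CCAAT` in -80..-30, otherwise the best single-mismatch
#' match, flagged `"hypothetical"`).  Coordinates are TSS-anchored
#' (negative).
#'
#' @param seq Nucleotide string containing at least 70 nt upstream of the
#'   TSS.
#' @param tss_offset 1-based array offset of position +1 in `seq`.
#' @param windows List with elements `tata`, `y_patch`, `caat`, each
#'   `c(lo, hi)` in TSS-anchored coordinates.
#' @return A list of class `core_elements` with entries `tata`, `y_patch`,
#'   `caat` (each `c(start, end)` or `NULL`) and `caat_status`
#'   (`"canonical"`, `"hypothetical"` or `NA`).
#' @export
find_core_elements <- function(seq, tss_offset,
                               windows = list(tata = c(-45L, -20L),
                                              y_patch = c(-60L, -10L),
                                              caat = c(-80L, -30L))) {
  seq <- toupper(seq)
  if (tss_offset - 1L < 70L)
    stop("need at least 70 nt upstream of the TSS")
  ch <- strsplit(seq, "")[[1L]]
  w_off <- function(w) {
    o <- pos_to_offset(w, tss_offset, nchar(seq))
    seq(min(o), max(o))
  }
  to_pos <- function(off) offset_to_pos(off, tss_offset)

  # TATA-box
  idx <- w_off(windows$tata)
  sub <- paste(ch[idx], collapse = "")
  m <- Biostrings::matchPattern("TATAWA", Biostrings::DNAString(sub),
                                fixed = "subject")
  tata <- NULL
  if (length(m)) {
    k <- which.max(Biostrings::end(m))
    tata <- to_pos(idx[1L] + c(Biostrings::start(m)[k],
                               Biostrings::end(m)[k]) - 1L)
  }

  # pyrimidine patch
  idx <- w_off(windows$y_patch)
  py <- ch[idx] %in% c("C", "T")
  r <- rle(py)
  y <- NULL
  if (any(r$values & r$lengths >= 5L)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= 5L)
    best <- cand[order(-r$lengths[cand], -ends[cand])][1L]
    y <- to_pos(idx[1L] + c(starts[best], ends[best]) - 1L)
  }

  # CAAT-box
  idx <- w_off(windows$caat)
  sub <- ch[idx]
  caat <- NULL; status <- NA_character_
  target <- c("C", "C", "A", "A", "T")
  nmm <- vapply(seq_len(length(sub) - 4L), function(i) {
    sum(sub[i:(i + 4L)] != target)
  }, integer(1))
  if (any(nmm == 0L)) {
    i <- max(which(nmm == 0L))
    caat <- to_pos(idx[1L] + c(i, i + 4L) - 1L); status <- "canonical"
  } else if (any(nmm == 1L)) {
    i <- max(which(nmm == 1L))
    caat <- to_pos(idx[1L] + c(i, i + 4L) - 1L); status <- "hypothetical"
  }

  structure(list(tata = tata, y_patch = y, caat = caat,
                 caat_status = status), class = "core_elements")
}

#' Detect motif occurrences disrupted by allelic variants
#'
#' A motif occurrence is disrupted in a genotype when at least one of that
#' genotype's variants has a footprint intersecting the occurrence's
#' normalized span.  A SNP's footprint is its single position; a deletion's
#' footprint covers its removed reference bases; an insertion's footprint
#' is the reference base before which the insertion sits.
#'
#' @param hits Motif hits from [scan_motifs()].
#' @param genotype_variants Named list mapping genotype labels to variant
#'   data frames (see [diff_haplotype()]).
#' @return Data frame with one row per disrupted (hit, genotype):
#'   `motif_id`, `start`, `end`, `strand`, `genotype`, `n_snps`,
#'   `n_indels`, `disruption_kind` (`"SNP"`, `"indel"` or `"both"`).
#' @export
detect_disruptions <- function(hits, genotype_variants) {
  out <- list()
  for (g in names(genotype_variants)) {
    v <- genotype_variants[[g]]
    if (is.null(v) || nrow(v) == 0L) next
    foot_lo <- v$position
    foot_hi <- ifelse(v$kind == "indel" & v$alt == "-",
                      v$position + v$length - 1L, v$position)
    for (i in seq_len(nrow(hits))) {
      lo <- hits$span_lo[i]; hi <- hits$span_hi[i]
      touch <- foot_lo <= hi & foot_hi >= lo
      if (!any(touch)) next
      kinds <- unique(v$kind[touch])
      out[[length(out) + 1L]] <- data.frame(
        motif_id = hits$motif_id[i], start = hits$start[i],
        end = hits$end[i], strand = hits$strand[i], genotype = g,
        n_snps = sum(v$kind[touch] == "SNP"),
        n_indels = sum(v$kind[touch] == "indel"),
        disruption_kind = if (length(kinds) == 2L) "both" else kinds)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else {
    data.frame(motif_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), genotype = character(0),
               n_snps = integer(0), n_indels = integer(0),
               disruption_kind = character(0))
  }
}
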