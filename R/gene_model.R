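# Gene models: a sequence with TSS-anchored coordinates, an ordered region
# annotation (promoter / 5'UTR / exons / introns / 3'UTR), and an
# exon-intron structure at the transcript level.

#' Construct a gene model
#'
#' A gene model couples a nucleotide sequence with a TSS-anchored coordinate
#' system and an ordered, gap-free region annotation.  Region coordinates are
#' TSS-anchored (promoter negative, first transcribed base +1, no position 0).
#'
#' @param gene_id Character label for the gene.
#' @param sequence Nucleotide string (A/C/G/T).
#' @param tss_index Array offset of the first transcribed base (position +1).
#' @param atg_pos TSS-anchored coordinate of the first base of the start
#'   codon, or `NULL` when unknown.
#' @param regions Data frame with columns `label`, `start`, `end`, `size`
#'   (TSS-anchored, inclusive) tiling the sequence in order, or `NULL`.
#' @param structure Optional transcript-level structure as returned by
#'   [infer_gene_structure()].
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, sequence, tss_index, atg_pos = NULL,
                       regions = NULL, structure = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) stop("sequence may contain only A/C/G/T")
  if (tss_index < 1L || tss_index > n) stop("tss_index outside sequence")
  if (!is.null(regions)) {
    offs <- cbind(pos_to_offset(regions$start, tss_index, n),
                  pos_to_offset(regions$end, tss_index, n))
    if (offs[1, 1] != 1L || offs[nrow(offs), 2] != n ||
        (nrow(offs) > 1L && any(offs[-1L, 1L] != offs[-nrow(offs), 2L] + 1L)))
      stop("regions must tile the sequence without gaps or overlaps")
    regions$size <- offs[, 2L] - offs[, 1L] + 1L
  }
  structure(list(gene_id = gene_id, sequence = sequence,
                 tss_index = as.integer(tss_index), atg_pos = atg_pos,
                 regions = regions, structure = structure),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, ": ", nchar(x$sequence), " nt, TSS at offset ",
      x$tss_index, if (!is.null(x$atg_pos)) paste0(", ATG at +", x$atg_pos),
      "\n", sep = "")
  if (!is.null(x$regions)) {
    cat("regions:\n")
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}

# Extract the sequence between two TSS-anchored coordinates (inclusive).
model_subseq <- function(model, start, end) {
  o <- pos_to_offset(c(start, end), model$tss_index, nchar(model$sequence))
  substr(model$sequence, o[1L], o[2L])
}

#' Annotate a gene model with the feature-wise region scheme
#'
#' Produces the region table used for SNP-density accounting: the promoter is
#' split into bins of `promoter_bin` nucleotides counting backwards from -1
#' (so the most-upstream bin may be short), the 5'UTR runs from +1 to the
#' base before the ATG, coding exons and introns are taken from the model's
#' regions, and the 3'UTR follows the stop codon.
#'
#' @param model A [gene_model()] whose `regions` are set.
#' @param promoter_bin Bin size in nucleotides for splitting the promoter;
#'   use `Inf` to keep the promoter as a single region.
#' @return Data frame with columns `label`, `start`, `end`, `size`.
#' @export
#' @examples
#' m <- build_reference(gsl1_model_spec())
#' annotate_regions(m, promoter_bin = 500)
annotate_regions <- function(model, promoter_bin = 500) {
  if (is.null(model$regions)) stop("model has no region annotation")
  reg <- model$regions
  out <- list()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    if (r$label == "promoter" && is.finite(promoter_bin) &&
        r$size > promoter_bin) {
      # bins counting backwards from -1; most-upstream bin may be short
      ends <- seq(-1L, r$start, by = -as.integer(promoter_bin))
      starts <- pmax(ends - as.integer(promoter_bin) + 1L, r$start)
      k <- length(ends)
      # rows (and bin indices) run upstream-first, matching reporting order
      bins <- data.frame(label = paste0("promoter_", seq_len(k)),
                         start = rev(starts), end = rev(ends))
      bins$size <- bins$end - bins$start + 1L
      out[[length(out) + 1L]] <- bins
    } else {
      out[[length(out) + 1L]] <-
        data.frame(label = r$label, start = r$start, end = r$end,
                   size = r$size)
    }
  }
  do.call(rbind, out)
}

#' Infer exon/intron structure from a genomic and a spliced (cDNA) sequence
#'
#' Finds a placement of the cDNA as an ordered, exact concatenation of
#' genomic substrings such that every skipped genomic segment is an intron of
#' at least `min_intron` nucleotides beginning with GT and ending with AG.
#' Among valid placements the leftmost one is returned: the first exon starts
#' as early as possible, then splice donors (and for equal donors, acceptors)
#' are taken as early as possible.
#'
#' @param genomic Genomic nucleotide string.
#' @param cdna Spliced transcript string (exact substring concatenation of
#'   `genomic`).
#' @param min_intron Minimum intron length in nucleotides (default 50; small
#'   values admit spurious GT..AG micro-introns in random sequence).
#' @param first_pos TSS-anchored coordinate of the first genomic base
#'   (default 1); reported coordinates use this anchor.
#' @return An object of class `gene_structure`: a list with data frames
#'   `exons` and `introns` (columns `start`, `end`, `size`, and for introns
#'   `donor`/`acceptor` dinucleotides).
#' @export
#' @examples
#' g <- paste0("ATGAAA", "GT", strrep("C", 50), "AG", "TTTTAA")
#' infer_gene_structure(g, "ATGAAATTTTAA", min_intron = 20)
infer_gene_structure <- function(genomic, cdna, min_intron = 50,
                                 first_pos = 1) {
  genomic <- toupper(genomic); cdna <- toupper(cdna)
  gl <- nchar(genomic); cl <- nchar(cdna)
  if (cl == 0L || gl == 0L) stop("sequences must be non-empty")
  g <- strsplit(genomic, "")[[1L]]
  cd <- strsplit(cdna, "")[[1L]]
  donor_at <- function(i) i + 1L <= gl && g[i] == "G" && g[i + 1L] == "T"
  acceptors <- which(g == "G") # intron end j has g[j-1] == "A", g[j] == "G"
  acceptors <- acceptors[acceptors > 1L]
  acceptors <- acceptors[g[acceptors - 1L] == "A"]

  failed <- new.env(hash = TRUE, parent = emptyenv())
  # DFS returning the list of intron (start, end) offset pairs, or NULL.
  # Preferring to open an intron before extending the exon yields the
  # placement with the lexicographically smallest donor positions.
  search <- function(gi, ci, in_exon) {
    key <- paste0(gi, ".", ci, ".", as.integer(in_exon > 0L))
    if (!is.null(failed[[key]])) return(NULL)
    if (ci > cl) return(list())
    if (gi > gl) { failed[[key]] <- TRUE; return(NULL) }
    # option 1: open an intron here (only mid-transcript, after >=1 exon base)
    if (in_exon > 0L && donor_at(gi)) {
      acc <- acceptors[acceptors >= gi + min_intron - 1L & acceptors < gl - (cl - ci)]
      for (j in acc) {
        sub <- search(j + 1L, ci, 0L)
        if (!is.null(sub)) return(c(list(c(gi, j)), sub))
      }
    }
    # option 2: extend the current exon
    if (g[gi] == cd[ci]) {
      sub <- search(gi + 1L, ci + 1L, in_exon + 1L)
      if (!is.null(sub)) return(sub)
    }
    failed[[key]] <- TRUE
    NULL
  }

  starts <- which(g == cd[1L])
  res <- NULL; exon1 <- NA_integer_
  for (s in starts) {
    res <- search(s + 1L, 2L, 1L)
    if (!is.null(res)) { exon1 <- s; break }
  }
  if (is.null(res))
    stop("no consistent exon placement with GT..AG introns of >= ",
         min_intron, " nt was found")

  pc <- tss_coords(first_pos, gl)
  if (length(res) == 0L) {
    exons <- data.frame(start = exon1, end = exon1 + cl - 1L)
    introns <- data.frame(start = integer(0), end = integer(0))
  } else {
    im <- do.call(rbind, res)
    ex_start <- c(exon1, im[, 2L] + 1L)
    ex_end <- c(im[, 1L] - 1L, exon1 + cl + sum(im[, 2L] - im[, 1L] + 1L) - 1L)
    exons <- data.frame(start = ex_start, end = ex_end)
    introns <- data.frame(start = im[, 1L], end = im[, 2L])
  }
  if (nrow(introns)) {
    introns$donor <- substring(genomic, introns$start, introns$start + 1L)
    introns$acceptor <- substring(genomic, introns$end - 1L, introns$end)
  } else {
    introns$donor <- character(0)
    introns$acceptor <- character(0)
  }
  exons$size <- exons$end - exons$start + 1L
  introns$size <- introns$end - introns$start + 1L
  exons$start <- pc[exons$start]; exons$end <- pc[exons$end]
  if (nrow(introns)) {
    introns$start <- pc[introns$start]; introns$end <- pc[introns$end]
  }
  structure(list(exons = exons,
                 introns = introns[, c("start", "end", "size",
                                       "donor", "acceptor")]),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("<gene_structure> ", nrow(x$exons), " exon(s), ", nrow(x$introns),
      " intron(s)\n", sep = "")
  cat("exons:\n"); print(x$exons, row.names = FALSE)
  if (nrow(x$introns)) { cat("introns:\n"); print(x$introns, row.names = FALSE) }
  invisible(x)
}

#' Spliced transcript of a gene model
#'
#' Concatenates the transcribed regions (5'UTR, exons, 3'UTR) of a model,
#' skipping introns, i.e. the mature transcript the model implies.
#'
#' @param model A [gene_model()] with regions.
#' @return Nucleotide string.
#' @export
spliced_transcript <- function(model) {
  if (is.null(model$regions)) stop("model has no region annotation")
  keep <- model$regions[!grepl("^(promoter|intron)", model$regions$label), ]
  paste(mapply(function(s, e) model_subseq(model, s, e), keep$start, keep$end),
        collapse = "")
}
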