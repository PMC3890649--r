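# Packaged motif fixtures: the key promoter motif libraries of the potato
# GSL1/GSL2 genes and their published occurrence tables, plus a builder
# that plants those occurrences into a synthetic promoter so the scanner
# can be exercised against known coordinates without any downloads.

gsl_extdata <- function(file) {
  path <- system.file("extdata", file, package = "polyhap")
  if (path == "") stop("packaged fixture not found: ", file)
  path
}

#' Packaged GSL promoter motif libraries and occurrence tables
#'
#' `gsl_motif_library()` returns the key degenerate motifs reported for the
#' *GSL1* (8 motifs) or *GSL2* (11 motifs) promoter.  `gsl_motif_hits()`
#' returns the published occurrence table for the DM reference promoter:
#' one row per occurrence with the concrete matched sequence, TSS-anchored
#' `start`/`end` in motif orientation (minus-strand rows have
#' `start > end`), `strand`, and the genotype letters recorded as carrying
#' disrupting polymorphisms (`"."` when none).
#'
#' @param gene `"GSL1"` or `"GSL2"`.
#' @return A [motif_library()] or a hits data frame.
#' @export
gsl_motif_library <- function(gene = c("GSL1", "GSL2")) {
  gene <- match.arg(gene)
  read_motif_library(gsl_extdata(sprintf("motifs_%s.tsv", tolower(gene))))
}

#' @rdname gsl_motif_library
#' @export
gsl_motif_hits <- function(gene = c("GSL1", "GSL2")) {
  gene <- match.arg(gene)
  read_tsv_skip_header(gsl_extdata(sprintf("motif_hits_%s.tsv",
                                           tolower(gene))))
}

# Convert occurrence rows into non-overlapping plus-strand segments,
# verifying that overlapping occurrences agree base by base.
merge_hit_segments <- function(hits) {
  base_at <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    plus <- if (hits$strand[i] == "+") hits$matched[i] else
      revcomp(hits$matched[i])
    lo <- min(hits$start[i], hits$end[i])
    letters <- strsplit(plus, "")[[1L]]
    pos <- tss_coords(lo, length(letters))
    for (k in seq_along(pos)) {
      key <- as.character(pos[k])
      prev <- base_at[[key]]
      if (!is.null(prev) && prev != letters[k])
        stop("occurrence table is internally inconsistent at position ",
             pos[k], ": ", prev, " vs ", letters[k])
      base_at[[key]] <- letters[k]
    }
  }
  pos <- sort(as.integer(ls(base_at)))
  if (!length(pos)) return(NULL)
  # contiguous runs under the no-zero convention (-1 is adjacent to +1)
  adjacent <- diff(pos) == 1L | (pos[-length(pos)] == -1L & pos[-1L] == 1L)
  run_id <- cumsum(c(1L, !adjacent))
  segs <- lapply(split(pos, run_id), function(p) {
    data.frame(start = p[1L], end = p[length(p)],
               seq = paste(vapply(as.character(p), function(k) base_at[[k]],
                                  character(1)), collapse = ""))
  })
  out <- do.call(rbind, segs)
  out$motif_id <- paste0("segment_", seq_len(nrow(out)))
  out$strand <- "+"
  rownames(out) <- NULL
  out
}

#' Synthetic DM-like promoter carrying the published motif occurrences
#'
#' Builds the corresponding GSL gene-model preset with every published
#' promoter motif occurrence planted at its printed TSS-anchored
#' coordinates (overlapping occurrences are merged into consistent
#' plus-strand segments first).  Scanning the returned model with
#' [gsl_motif_library()] recovers all printed occurrences.
#'
#' @param gene `"GSL1"` or `"GSL2"`.
#' @param seed Integer seed for the background sequence.
#' @return A [gene_model()].
#' @export
#' @examples
#' m <- gsl_promoter_fixture("GSL2")
#' hits <- scan_motifs(m, gsl_motif_library("GSL2"))
gsl_promoter_fixture <- function(gene = c("GSL1", "GSL2"), seed = 1L) {
  gene <- match.arg(gene)
  segs <- merge_hit_segments(gsl_motif_hits(gene))
  base <- if (gene == "GSL1") gsl1_model_spec(seed) else gsl2_model_spec(seed)
  spec <- gene_model_spec(gene_id = paste0(gene, "_DM_like"),
                          regions = base$regions, gc = base$gc,
                          planted_motifs = segs[, c("motif_id", "seq",
                                                    "start", "end", "strand")],
                          core_elements = NULL, seed = seed)
  build_reference(spec)
}
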