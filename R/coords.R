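# TSS-anchored coordinate system.
#
# User-facing coordinates are 1-based and inclusive, anchored at the
# transcription start site: the first transcribed base is +1, the base
# immediately upstream is -1, and there is no position 0.  Internally all
# computation uses plain 1-based array offsets into the sequence.

#' Convert TSS-anchored positions to array offsets
#'
#' @param pos Integer vector of TSS-anchored positions (no zero allowed;
#'   negative values are upstream of the TSS).
#' @param tss_index Array offset of position +1 (the first transcribed base).
#' @param n Optional sequence length; when given, offsets outside `1..n`
#'   raise an error.
#' @return Integer vector of 1-based array offsets.
#' @seealso [offset_to_pos()]
#' @export
#' @examples
#' pos_to_offset(c(-1, 1), tss_index = 100)
pos_to_offset <- function(pos, tss_index, n = NULL) {
  pos <- as.integer(pos)
  if (anyNA(pos)) stop("positions must not be NA")
  if (any(pos == 0L)) stop("position 0 does not exist: -1 is followed by +1")
  off <- ifelse(pos > 0L, tss_index + pos - 1L, tss_index + pos)
  if (!is.null(n) && (any(off < 1L) || any(off > n))) {
    bad <- pos[off < 1L | off > n][1L]
    stop("position ", bad, " is outside the sequence")
  }
  as.integer(off)
}

#' Convert array offsets to TSS-anchored positions
#'
#' Inverse of [pos_to_offset()].
#'
#' @param off Integer vector of 1-based array offsets.
#' @param tss_index Array offset of position +1.
#' @return Integer vector of TSS-anchored positions (never 0).
#' @export
offset_to_pos <- function(off, tss_index) {
  off <- as.integer(off)
  if (any(off < 1L)) stop("array offsets must be >= 1")
  as.integer(ifelse(off >= tss_index, off - tss_index + 1L, off - tss_index))
}

# Consecutive TSS-anchored coordinates for a sequence of length n whose
# first base has coordinate `first_pos`.  Skips 0.
tss_coords <- function(first_pos, n) {
  first_pos <- as.integer(first_pos)
  if (first_pos == 0L) stop("position 0 does not exist")
  raw <- first_pos + seq_len(n) - 1L
  as.integer(ifelse(first_pos < 0L & raw >= 0L, raw + 1L, raw))
}
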