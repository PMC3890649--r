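# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# --- alignment oracles ------------------------------------------------------

# Independent Gotoh dynamic program (three-state affine DP written from the
# recurrences, not via Biostrings).  Gap of length L costs open + L * extend.
oracle_gotoh_score <- function(a, b, match = 2, mismatch = -3,
                               open = 5, extend = 2) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (b consumed)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                               X[i, j + 1L] - extend,
                               Y[i, j + 1L] - open - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                               Y[i + 1L, j] - extend,
                               X[i + 1L, j] - open - extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Exhaustive enumeration over all global alignments (move sequences), for
# very short sequences only.  Validates the Gotoh helper itself.
oracle_enum_score <- function(a, b, match = 2, mismatch = -3,
                              open = 5, extend = 2) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, acc); return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      rec(i + 1L, j + 1L, "M", acc + s)
    }
    if (i <= length(av)) {
      rec(i + 1L, j, "X", acc - extend - if (prev == "X") 0 else open)
    }
    if (j <= length(bv)) {
      rec(i, j + 1L, "Y", acc - extend - if (prev == "Y") 0 else open)
    }
  }
  rec(1L, 1L, "start", 0)
  best
}

# --- degenerate motif oracle ------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Expand a degenerate pattern to the explicit set of concrete words.
oracle_expand_pattern <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1L]]]
  apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)), 1L,
        function(r) paste(rev(r), collapse = ""))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
}

# All (offset_start, offset_end, strand) occurrences by explicit expansion
# and naive substring search.
oracle_scan <- function(seq, pattern) {
  L <- nchar(pattern); n <- nchar(seq)
  words <- oracle_expand_pattern(pattern)
  hits <- list()
  for (i in seq_len(n - L + 1L)) {
    sub <- substr(seq, i, i + L - 1L)
    if (sub %in% words)
      hits[[length(hits) + 1L]] <- c(i, i + L - 1L, 1L)
    if (oracle_revcomp(sub) %in% words)
      hits[[length(hits) + 1L]] <- c(i, i + L - 1L, -1L)
  }
  if (!length(hits))
    return(data.frame(lo = integer(0), hi = integer(0), strand = integer(0)))
  m <- do.call(rbind, hits)
  data.frame(lo = m[, 1L], hi = m[, 2L], strand = m[, 3L])
}

# --- splice placement oracle ------------------------------------------------

# Enumerate every placement of cdna as ordered exact genomic substrings with
# GT..AG introns of >= min_intron nt.  Returns a list of placements, each a
# data frame of exon (start, end) offsets.  Exponential; tiny inputs only.
oracle_splice_placements <- function(genomic, cdna, min_intron) {
  g <- strsplit(genomic, "")[[1L]]; cd <- strsplit(cdna, "")[[1L]]
  gl <- length(g); cl <- length(cd)
  out <- list()
  rec <- function(gi, ci, exon_start, bounds) {
    if (ci > cl) {
      out[[length(out) + 1L]] <<- rbind(bounds, c(exon_start, gi - 1L))
      return(invisible())
    }
    if (gi > gl) return(invisible())
    if (g[gi] == cd[ci]) rec(gi + 1L, ci + 1L, exon_start, bounds)
    if (gi > exon_start) { # an exon must have >= 1 base before a donor
      if (gi + 1L <= gl && g[gi] == "G" && g[gi + 1L] == "T") {
        jmin <- gi + min_intron - 1L
        jmax <- gl - (cl - ci + 1L)
        if (jmin <= jmax) {
          for (j in jmin:jmax) {
            if (j > 1L && g[j - 1L] == "A" && g[j] == "G")
              rec(j + 1L, ci, j + 1L, rbind(bounds, c(exon_start, gi - 1L)))
          }
        }
      }
    }
  }
  for (s in which(g == cd[1L])) rec(s + 1L, 2L, s, NULL)
  out
}

# Lexicographically smallest placement by (exon1 start, donor positions...).
oracle_leftmost_placement <- function(placements) {
  keys <- lapply(placements, function(p) as.vector(t(p)))
  ord <- do.call(order, as.data.frame(do.call(rbind, lapply(keys, function(k) {
    length(k) <- max(lengths(keys)); k[is.na(k)] <- 1e9; k  # fewer introns last
  }))))
  placements[[ord[1L]]]
}

# --- dosage oracle ----------------------------------------------------------

# Compositions via expand.grid, likelihood via dmultinom: fully independent
# of the package's enumeration and log-likelihood code.
oracle_best_dosage <- function(counts, ploidy = 4L, min_copies = 1L) {
  k <- length(counts)
  grid <- do.call(expand.grid, rep(list(min_copies:ploidy), k))
  grid <- grid[rowSums(grid) == ploidy, , drop = FALSE]
  ll <- apply(grid, 1, function(d) {
    if (any(counts > 0 & d == 0)) return(-Inf)
    stats::dmultinom(counts, prob = d / ploidy, log = TRUE)
  })
  as.integer(grid[which.max(ll), ])
}

# --- misc -------------------------------------------------------------------

# Independent variant application by character-vector surgery.
oracle_apply_variants <- function(refseq, variants, tss_index) {
  ch <- strsplit(refseq, "")[[1L]]
  off <- ifelse(variants$position > 0, tss_index + variants$position - 1L,
                tss_index + variants$position)
  pieces <- as.list(ch)
  for (i in seq_len(nrow(variants))) {
    p <- off[i]
    if (variants$kind[i] == "SNP") {
      pieces[[p]] <- variants$alt[i]
    } else if (variants$ref[i] == "-") {
      pieces[[p]] <- c(variants$alt[i], pieces[[p]])
    } else {
      for (k in p:(p + variants$length[i] - 1L)) pieces[[k]] <- character(0)
    }
  }
  paste(unlist(pieces), collapse = "")
}
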