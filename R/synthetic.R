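# Synthetic data: gene models with planted promoter features, tetraploid
# haplotype sets with controlled per-region SNP/indel counts, pre-placed
# short reads with phred qualities, and clone sampling from allele dosages.

DNA <- c("A", "C", "G", "T")
IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

# One concrete realization of an IUPAC pattern (degenerate letters sampled).
realize_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1L]]
  bad <- setdiff(letters, names(IUPAC_MAP))
  if (length(bad)) stop("invalid IUPAC character: ", bad[1L])
  paste(vapply(letters, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Specify a synthetic gene model
#'
#' Describes a gene to be generated by [build_reference()]: ordered region
#' lengths, GC content of the background sequence, promoter motifs to plant
#' at fixed TSS-anchored coordinates, and core promoter elements (TATA-box,
#' pyrimidine patch, CAAT-box) to plant upstream of the TSS.
#'
#' @param gene_id Character label.
#' @param regions Data frame with columns `label` (one of `promoter`, `utr5`,
#'   `exon_k`, `intron_k`, `utr3`) and `length` (nt), in genomic order.
#' @param gc GC fraction of the i.i.d. background sequence, in `[0, 1]`.
#' @param planted_motifs `NULL`, or a data frame with columns `motif_id`,
#'   `seq` (IUPAC; degenerate letters are realized concretely), `start`,
#'   `end`, `strand`.  Coordinates are TSS-anchored in the motif's own 5'->3'
#'   orientation, so minus-strand rows have `start > end`.
#' @param core_elements `NULL`, or a list with optional entries `tata`,
#'   `y_patch`, `caat` (each `c(start, end)` upstream of the TSS, negative)
#'   and logical `caat_mismatch` (plant a near-match CAAT-box instead of a
#'   canonical CCAAT).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `gene_model_spec`.
#' @export
gene_model_spec <- function(gene_id = "synthetic_gene", regions,
                            gc = 0.5, planted_motifs = NULL,
                            core_elements = NULL, seed = 1L) {
  stopifnot(is.data.frame(regions), all(c("label", "length") %in% names(regions)))
  if (any(regions$length <= 0)) stop("region lengths must be positive")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!any(regions$label == "utr5"))
    stop("a 'utr5' region is required to anchor the TSS")
  spec <- structure(list(gene_id = gene_id, regions = regions, gc = gc,
                         planted_motifs = planted_motifs,
                         core_elements = core_elements,
                         seed = as.integer(seed)),
                    class = "gene_model_spec")
  validate_planted(spec)
  spec
}

# Normalized spans (lo, hi TSS-anchored) of all planted features; errors on
# overlap, naming the conflicting pair.
validate_planted <- function(spec) {
  feats <- data.frame(name = character(0), lo = integer(0), hi = integer(0))
  pm <- spec$planted_motifs
  if (!is.null(pm)) {
    feats <- rbind(feats, data.frame(
      name = paste0(pm$motif_id, "@", pm$start),
      lo = pmin(pm$start, pm$end), hi = pmax(pm$start, pm$end)))
  }
  ce <- spec$core_elements
  for (nm in intersect(c("tata", "y_patch", "caat"), names(ce))) {
    sp <- ce[[nm]]
    feats <- rbind(feats, data.frame(name = nm, lo = min(sp), hi = max(sp)))
  }
  if (nrow(feats) > 1L) {
    o <- order(feats$lo)
    feats <- feats[o, ]
    for (i in seq_len(nrow(feats) - 1L)) {
      if (feats$hi[i] >= feats$lo[i + 1L])
        stop("planted features overlap: ", feats$name[i], " and ",
             feats$name[i + 1L])
    }
  }
  prom <- spec$regions$length[spec$regions$label == "promoter"]
  prom <- if (length(prom)) prom else 0L
  if (nrow(feats) && (any(feats$lo < -prom)))
    stop("planted feature extends beyond the promoter")
  invisible(spec)
}

#' Build a reference gene model from a spec
#'
#' Generates an i.i.d. background sequence at the requested GC content, then
#' overwrites fixed features onto it: ATG at the first coding exon, a stop
#' codon at the end of the last coding exon, GT/AG dinucleotides at intron
#' boundaries, a pyrimidine-purine dimer across the TSS (-1/+1), planted
#' promoter motifs at their declared coordinates, and core promoter
#' elements.  When core elements are planted, the core window (-80..-10) is
#' first filled with purines so that the planted elements are the unique
#' matches there.
#'
#' @param spec A [gene_model_spec()].
#' @return A [gene_model()] whose regions tile the generated sequence.
#' @export
#' @examples
#' m <- build_reference(gsl1_model_spec())
#' nchar(m$sequence)
build_reference <- function(spec) {
  stopifnot(inherits(spec, "gene_model_spec"))
  set.seed(spec$seed)
  reg <- spec$regions
  n <- sum(reg$length)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  s <- sample(DNA, n, replace = TRUE, prob = p[DNA])

  ends <- cumsum(reg$length)
  starts <- ends - reg$length + 1L
  prom_len <- sum(reg$length[reg$label == "promoter"])
  tss_index <- prom_len + 1L
  pos2off <- function(pos) pos_to_offset(pos, tss_index, n)

  # splice dinucleotides
  for (i in which(grepl("^intron", reg$label))) {
    s[starts[i]] <- "G"; s[starts[i] + 1L] <- "T"
    s[ends[i] - 1L] <- "A"; s[ends[i]] <- "G"
  }
  # start / stop codons
  exon_idx <- which(grepl("^exon", reg$label))
  atg_pos <- NULL
  if (length(exon_idx)) {
    a <- starts[exon_idx[1L]]
    s[a] <- "A"; s[a + 1L] <- "T"; s[a + 2L] <- "G"
    atg_pos <- offset_to_pos(a, tss_index)
    z <- ends[exon_idx[length(exon_idx)]]
    s[z - 2L] <- "T"; s[z - 1L] <- "A"; s[z] <- "A"
  }
  # pyrimidine-purine dimer across the TSS
  if (prom_len > 0L) { s[tss_index - 1L] <- "T"; s[tss_index] <- "G" }

  # core promoter elements on a purine background
  ce <- spec$core_elements
  if (!is.null(ce) && prom_len >= 80L) {
    win <- pos2off(seq(-80L, -10L))
    s[win] <- sample(c("A", "G"), length(win), replace = TRUE)
    s[tss_index - 1L] <- "T"
    if (!is.null(ce$tata)) {
      o <- pos2off(ce$tata)
      if (abs(o[2L] - o[1L]) + 1L != 6L) stop("tata span must be 6 nt")
      s[seq(min(o), max(o))] <- c("T", "A", "T", "A",
                                  sample(c("A", "T"), 1L), "A")
    }
    if (!is.null(ce$y_patch)) {
      o <- pos2off(ce$y_patch)
      idx <- seq(min(o), max(o))
      if (length(idx) < 5L) stop("y_patch span must be >= 5 nt")
      s[idx] <- sample(c("C", "T"), length(idx), replace = TRUE)
    }
    if (!is.null(ce$caat)) {
      o <- pos2off(ce$caat)
      idx <- seq(min(o), max(o))
      if (length(idx) != 5L) stop("caat span must be 5 nt")
      el <- c("C", "C", "A", "A", "T")
      if (isTRUE(ce$caat_mismatch)) el[1L] <- "A"
      s[idx] <- el
    }
  }

  # planted promoter motifs (plus-strand representation)
  pm <- spec$planted_motifs
  if (!is.null(pm)) {
    for (i in seq_len(nrow(pm))) {
      conc <- realize_iupac(pm$seq[i])
      plus <- if (pm$strand[i] == "+") conc else revcomp(conc)
      lo <- min(pm$start[i], pm$end[i]); hi <- max(pm$start[i], pm$end[i])
      idx <- seq(pos2off(lo), pos2off(hi))
      if (length(idx) != nchar(plus))
        stop("motif ", pm$motif_id[i], " span does not match its length")
      s[idx] <- strsplit(plus, "")[[1L]]
    }
  }

  regions <- data.frame(label = reg$label,
                        start = offset_to_pos(starts, tss_index),
                        end = offset_to_pos(ends, tss_index),
                        size = reg$length)
  # collapse consecutive promoter rows (if a caller split them) is not done:
  # the spec's region list is taken as-is.
  gene_model(spec$gene_id, paste(s, collapse = ""), tss_index,
             atg_pos = atg_pos, regions = regions)
}

#' GSL1-like and GSL2-like gene model specs
#'
#' Presets matching the published feature sizes of the potato *GSL1* and
#' *GSL2* genes: for *GSL1* a 1960 nt promoter, 33 nt 5'UTR, exons of 82 and
#' 185 nt separated by a 504 nt intron, and a 205 nt 3'UTR; for *GSL2* a
#' 590 nt promoter, 38 nt 5'UTR, exons of 87/46/182 nt, introns of 249 and
#' 163 nt, and a 302 nt 3'UTR.  Core promoter elements are planted at the
#' annotated coordinates (TATA-box -32..-27, Y patch -26..-20, CAAT-box
#' -48..-44 for *GSL1*; TATA-box -50..-45, Y patch -59..-51 and a
#' near-match "hypothetical" CAAT-box -65..-61 for *GSL2*).
#'
#' @param seed Integer seed passed to [gene_model_spec()].
#' @return A [gene_model_spec()].
#' @export
gsl1_model_spec <- function(seed = 1L) {
  gene_model_spec(
    gene_id = "GSL1",
    regions = data.frame(
      label = c("promoter", "utr5", "exon_1", "intron_1", "exon_2", "utr3"),
      length = c(1960L, 33L, 82L, 504L, 185L, 205L)),
    core_elements = list(tata = c(-32L, -27L), y_patch = c(-26L, -20L),
                         caat = c(-48L, -44L)),
    seed = seed)
}

#' @rdname gsl1_model_spec
#' @export
gsl2_model_spec <- function(seed = 1L) {
  gene_model_spec(
    gene_id = "GSL2",
    regions = data.frame(
      label = c("promoter", "utr5", "exon_1", "intron_1", "exon_2",
                "intron_2", "exon_3", "utr3"),
      length = c(590L, 38L, 87L, 249L, 46L, 163L, 182L, 302L)),
    core_elements = list(tata = c(-50L, -45L), y_patch = c(-59L, -51L),
                         caat = c(-65L, -61L), caat_mismatch = TRUE),
    seed = seed)
}

#' Published per-region variant counts for the GSL presets
#'
#' The merged SNP and indel counts per gene feature (promoter in 500 nt bins
#' for *GSL1*, single 590 nt promoter for *GSL2*) observed across all
#' re-sequenced potato genotypes.  Labels match
#' `annotate_regions(model, promoter_bin)` on the corresponding preset.
#'
#' @return Data frame with columns `label`, `n_snps`, `n_indels`.
#' @export
gsl1_region_counts <- function() {
  data.frame(
    label = c("promoter_1", "promoter_2", "promoter_3", "promoter_4",
              "utr5", "exon_1", "intron_1", "exon_2", "utr3"),
    n_snps = c(18L, 14L, 18L, 13L, 1L, 2L, 24L, 2L, 5L),
    n_indels = c(6L, 9L, 9L, 10L, 0L, 0L, 16L, 0L, 3L))
}

#' @rdname gsl1_region_counts
#' @export
gsl2_region_counts <- function() {
  data.frame(
    label = c("promoter", "utr5", "exon_1", "intron_1", "exon_2",
              "intron_2", "exon_3", "utr3"),
    n_snps = c(12L, 0L, 1L, 7L, 1L, 5L, 4L, 6L),
    n_indels = c(6L, 1L, 0L, 2L, 0L, 5L, 0L, 7L))
}

# Draw n variant anchor positions inside [lo, hi] (array offsets) such that
# footprints (fp[i] nt from the anchor) are separated by >= sep.  Uses the
# stars-and-bars construction, so success is guaranteed when capacity allows.
place_positions <- function(lo, hi, fp, sep, region_label) {
  n <- length(fp)
  if (n == 0L) return(integer(0))
  req <- fp + sep
  free <- (hi - lo + 1L) - sum(req)
  if (free < 0L)
    stop("region '", region_label, "' is too small for ", n,
         " variants with the configured footprints")
  u <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
  lo + u + cumsum(req) - req
}

#' Derive mutated haplotypes from a reference model
#'
#' Plants exactly the requested number of SNPs and indels in each annotated
#' region, assigns each variant to a random non-empty subset of the mutated
#' haplotypes (haplotype `hap0` stays identical to the reference), and
#' returns both the haplotype sequences and the ground-truth variant table.
#' Variant footprints are kept at least `min_sep` nucleotides apart and
#' `margin` nucleotides away from region boundaries so that alignment-based
#' re-discovery is unambiguous.
#'
#' @param model A [gene_model()] from [build_reference()].
#' @param counts Data frame with columns `label`, `n_snps`, `n_indels`; the
#'   labels must match `regions$label`.
#' @param regions Region table the counts refer to (default
#'   `annotate_regions(model)`).
#' @param n_haplotypes Total number of haplotypes including the unmutated
#'   `hap0` (default 4, a tetraploid).
#' @param indel_len Integer range `c(min, max)` of indel lengths (nt).
#' @param min_sep Minimum separation between variant footprints (nt).
#' @param margin Minimum distance from a region boundary (nt); shrunk
#'   automatically in regions too small to honour it.
#' @param seed Integer seed.
#' @param verify_recovery When indels are planted, check that alignment-based
#'   re-discovery ([diff_haplotype()] + [merge_variant_tables()]) reproduces
#'   the requested per-region counts exactly, and re-draw the placement when
#'   it does not (closely spaced indels can otherwise admit an equally or
#'   better scoring alignment that miscounts events).  Deterministic given
#'   the seed.
#' @return A list with `haplotypes` (named character vector, `hap0` first)
#'   and `truth` (variant data frame; see [diff_haplotype()] for the
#'   column convention).
#' @export
spawn_haplotypes <- function(model, counts, regions = annotate_regions(model),
                             n_haplotypes = 4L, indel_len = c(1L, 7L),
                             min_sep = 8L, margin = 8L, seed = 1L,
                             verify_recovery = TRUE) {
  stopifnot(inherits(model, "gene_model"))
  if (!all(counts$label %in% regions$label))
    stop("counts refer to unknown region label: ",
         setdiff(counts$label, regions$label)[1L])
  set.seed(seed)
  for (attempt in seq_len(50L)) {
    res <- spawn_once(model, counts, regions, n_haplotypes, indel_len,
                      min_sep, margin)
    if (!verify_recovery || !any(res$truth$kind == "indel")) return(res)
    if (recovery_exact(model, res$haplotypes, counts, regions)) return(res)
  }
  stop("could not plant an unambiguously recoverable variant set; ",
       "reduce the requested density or indel lengths")
}

# check that diff -> merge -> summarize reproduces the requested counts
recovery_exact <- function(model, haplotypes, counts, regions) {
  tabs <- lapply(names(haplotypes)[-1L], function(h)
    diff_haplotype(model$sequence, haplotypes[[h]],
                   tss_index = model$tss_index, gene_id = model$gene_id,
                   carrier = h))
  s <- tryCatch(summarize_regions(merge_variant_tables(tabs), regions),
                error = function(e) NULL)
  if (is.null(s)) return(FALSE)
  want_s <- want_i <- stats::setNames(integer(nrow(regions)), regions$label)
  want_s[counts$label] <- counts$n_snps
  want_i[counts$label] <- counts$n_indels
  all(s$n_snps == want_s[s$label]) && all(s$n_indels == want_i[s$label])
}

spawn_once <- function(model, counts, regions, n_haplotypes, indel_len,
                       min_sep, margin) {
  n <- nchar(model$sequence)
  refch <- strsplit(model$sequence, "")[[1L]]

  vars <- list()
  for (i in seq_len(nrow(counts))) {
    lab <- counts$label[i]
    ns <- counts$n_snps[i]; ni <- counts$n_indels[i]
    if (ns + ni == 0L) next
    r <- regions[regions$label == lab, ]
    o <- pos_to_offset(c(r$start, r$end), model$tss_index, n)
    kinds <- sample(c(rep("SNP", ns), rep("indel", ni)))
    lens <- ifelse(kinds == "SNP", 1L,
                   sample(seq(indel_len[1L], indel_len[2L]), ns + ni,
                          replace = TRUE))
    ins <- kinds == "indel" & sample(c(TRUE, FALSE), ns + ni, replace = TRUE)
    fp <- ifelse(kinds == "SNP", 1L, ifelse(ins, 1L, lens))
    m <- margin
    while (m > 1L && (o[2L] - o[1L] + 1L - 2L * m) < sum(fp + min_sep)) {
      m <- m %/% 2L
    }
    pos <- place_positions(o[1L] + m, o[2L] - m, fp, min_sep, lab)
    for (j in seq_along(pos)) {
      p <- pos[j]
      if (kinds[j] == "SNP") {
        alt <- sample(setdiff(DNA, refch[p]), 1L)
        vars[[length(vars) + 1L]] <- data.frame(
          position = p, kind = "SNP", ref = refch[p], alt = alt, length = 1L)
      } else if (ins[j]) {
        insseq <- sample(DNA, lens[j], replace = TRUE)
        # avoid single-base slides: inserted run must not extend flanking bases
        if (insseq[1L] == refch[p]) insseq[1L] <- sample(setdiff(DNA, refch[p]), 1L)
        if (insseq[lens[j]] == refch[p - 1L])
          insseq[lens[j]] <- sample(setdiff(DNA, refch[p - 1L]), 1L)
        vars[[length(vars) + 1L]] <- data.frame(
          position = p, kind = "indel", ref = "-",
          alt = paste(insseq, collapse = ""), length = lens[j])
      } else {
        vars[[length(vars) + 1L]] <- data.frame(
          position = p, kind = "indel",
          ref = paste(refch[p:(p + lens[j] - 1L)], collapse = ""), alt = "-",
          length = lens[j])
      }
    }
  }

  hap_names <- paste0("hap", seq_len(n_haplotypes) - 1L)
  truth <- if (length(vars)) do.call(rbind, vars) else
    data.frame(position = integer(0), kind = character(0),
               ref = character(0), alt = character(0), length = integer(0))
  if (nrow(truth)) {
    truth <- truth[order(truth$position), , drop = FALSE]
    carriers <- vapply(seq_len(nrow(truth)), function(i) {
      k <- sample.int(n_haplotypes - 1L, 1L)
      paste(sort(sample(hap_names[-1L], k)), collapse = ",")
    }, character(1))
    truth$carriers <- carriers
  } else {
    truth$carriers <- character(0)
  }
  truth$gene_id <- rep(model$gene_id, nrow(truth))
  truth$position <- offset_to_pos(truth$position, model$tss_index)
  truth <- truth[, c("gene_id", "position", "kind", "ref", "alt",
                     "length", "carriers")]
  rownames(truth) <- NULL

  haps <- vapply(hap_names, function(h) {
    if (h == "hap0") return(model$sequence)
    mine <- truth[vapply(strsplit(truth$carriers, ","),
                         function(cs) h %in% cs, logical(1)), , drop = FALSE]
    apply_variants(model$sequence, mine, tss_index = model$tss_index)
  }, character(1))
  list(haplotypes = haps, truth = truth)
}

#' Apply a variant table to a reference sequence
#'
#' Reconstructs a haplotype by applying SNPs and indels (in TSS-anchored
#' coordinates) to the reference.  An insertion with `ref == "-"` is placed
#' immediately before its `position`; a deletion removes `length` bases
#' starting at `position`.
#'
#' @param sequence Reference nucleotide string.
#' @param variants Variant data frame (columns `position`, `kind`, `ref`,
#'   `alt`, `length`).
#' @param tss_index Array offset of position +1 in `sequence`.
#' @return The mutated sequence.
#' @export
apply_variants <- function(sequence, variants, tss_index = 1L) {
  if (nrow(variants) == 0L) return(sequence)
  n <- nchar(sequence)
  off <- pos_to_offset(variants$position, tss_index, n)
  ord <- order(off, decreasing = TRUE)
  s <- sequence
  for (i in ord) {
    p <- off[i]
    if (variants$kind[i] == "SNP") {
      substr(s, p, p) <- variants$alt[i]
    } else if (variants$ref[i] == "-") {
      s <- paste0(substr(s, 1L, p - 1L), variants$alt[i],
                  substr(s, p, nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, p - 1L),
                  substr(s, p + variants$length[i], nchar(s)))
    }
  }
  s
}

#' Configure the short-read simulator
#'
#' @param read_length Read length in nt.
#' @param coverage Target mean fold-coverage of the locus (the study design
#'   this emulates used roughly 9-15x).
#' @param base_error_rate Per-base probability of a miscalled base.
#' @param qual_mean,qual_sd Mean and standard deviation of simulated phred
#'   base qualities (normal, rounded, clamped to 2..41).
#' @param nonunique_fraction Fraction of reads flagged as multiply mapped.
#' @param placement `"tiled"` places read starts evenly so that every
#'   interior position receives its expected coverage deterministically;
#'   `"random"` draws starts uniformly.
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 100L, coverage = 12,
                            base_error_rate = 0, qual_mean = 35,
                            qual_sd = 3, nonunique_fraction = 0,
                            placement = c("tiled", "random"), seed = 1L) {
  if (base_error_rate < 0 || base_error_rate >= 1)
    stop("base_error_rate must be in [0, 1)")
  if (coverage <= 0) stop("coverage must be positive")
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 base_error_rate = base_error_rate, qual_mean = qual_mean,
                 qual_sd = qual_sd, nonunique_fraction = nonunique_fraction,
                 placement = match.arg(placement), seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate pre-placed short reads from a haplotype mixture
#'
#' Emits single-end reads from the haplotypes of a genotype, with the number
#' of reads per haplotype proportional to its dosage (copy number).  Reads
#' carry their true placement (TSS-anchored coordinate of the first base),
#' per-base phred qualities and a unique-mapping flag; no mapping is
#' performed.  Haplotypes must be SNP-only (same length as the reference):
#' indel-carrying haplotypes shift coordinates and are rejected.
#'
#' @param model A [gene_model()] (the reference the coordinates refer to).
#' @param haplotypes Named character vector of haplotype sequences.
#' @param dosage Integer copy number per haplotype; `sum(dosage)` is the
#'   ploidy.
#' @param cfg A [read_sim_config()].
#' @return Data frame with columns `read_id`, `hap`, `start` (TSS-anchored),
#'   `strand`, `seq`, `qual` (phred+33 string), `unique_flag`.
#' @export
simulate_reads <- function(model, haplotypes, dosage,
                           cfg = read_sim_config()) {
  stopifnot(inherits(model, "gene_model"))
  if (length(dosage) != length(haplotypes))
    stop("dosage must have one entry per haplotype")
  if (any(dosage < 0)) stop("dosage entries must be >= 0")
  ploidy <- sum(dosage)
  if (ploidy == 0L) stop("ploidy (sum of dosage) must be >= 1")
  L <- nchar(model$sequence)
  if (any(nchar(haplotypes) != L))
    stop("haplotypes must be SNP-only (same length as the reference)")
  rl <- cfg$read_length
  if (rl > L) stop("read length exceeds the locus length")
  set.seed(cfg$seed)

  starts_list <- list(); hap_list <- list()
  if (cfg$placement == "tiled") {
    cov_copy <- cfg$coverage / ploidy
    step <- rl / cov_copy
    base_starts <- unique(c(round(seq(1, L - rl + 1, by = step)), L - rl + 1L))
    for (h in seq_along(haplotypes)) {
      if (dosage[h] == 0) next
      st <- rep(base_starts, dosage[h])
      starts_list[[length(starts_list) + 1L]] <- st
      hap_list[[length(hap_list) + 1L]] <- rep(h, length(st))
    }
  } else {
    n_reads <- round(cfg$coverage * L / rl)
    h <- sample.int(length(haplotypes), n_reads, replace = TRUE,
                    prob = dosage / ploidy)
    starts_list[[1L]] <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    hap_list[[1L]] <- h
  }
  start <- unlist(starts_list); hap <- unlist(hap_list)
  nr <- length(start)
  hap_names <- if (!is.null(names(haplotypes))) names(haplotypes) else
    paste0("hap", seq_along(haplotypes) - 1L)

  seqs <- substring(haplotypes[hap], start, start + rl - 1L)
  if (cfg$base_error_rate > 0) {
    mat <- matrix(unlist(strsplit(seqs, "")), nrow = rl)
    err <- matrix(stats::runif(rl * nr) < cfg$base_error_rate, nrow = rl)
    if (any(err)) {
      idx <- which(err)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      mat[idx] <- DNA[(match(mat[idx], DNA) - 1L + shift) %% 4L + 1L]
    }
    seqs <- apply(mat, 2L, paste, collapse = "")
  }
  q <- matrix(pmin(pmax(round(stats::rnorm(rl * nr, cfg$qual_mean,
                                           cfg$qual_sd)), 2L), 41L),
              nrow = rl)
  quals <- apply(q + 33L, 2L, intToUtf8)
  data.frame(
    read_id = sprintf("r%06d", seq_len(nr)),
    hap = hap_names[hap],
    start = offset_to_pos(start, model$tss_index),
    strand = sample(c("+", "-"), nr, replace = TRUE),
    seq = seqs,
    qual = quals,
    unique_flag = as.integer(stats::runif(nr) >= cfg$nonunique_fraction))
}

#' Sample sequencing clones from an allele dosage
#'
#' Multinomial clone sampling: each of `n_clones` cloned PCR products is an
#' independent draw of one allele with probability proportional to its copy
#' number.
#'
#' @param dosage Named (or unnamed) non-negative integer vector of allele
#'   copy numbers.
#' @param n_clones Number of clones sequenced.
#' @param seed Integer seed.
#' @return Named integer vector of clone counts summing to `n_clones`.
#' @export
#' @examples
#' sample_clones(c(a1 = 3, a2 = 1), n_clones = 16, seed = 7)
sample_clones <- function(dosage, n_clones, seed = 1L) {
  if (any(dosage < 0)) stop("dosage entries must be >= 0")
  if (sum(dosage) < 1) stop("sum of dosage must be >= 1")
  if (n_clones < 1) stop("n_clones must be >= 1")
  set.seed(seed)
  cts <- as.integer(stats::rmultinom(1L, n_clones, prob = dosage / sum(dosage)))
  names(cts) <- if (!is.null(names(dosage))) names(dosage) else
    paste0("allele", seq_along(dosage))
  cts
}
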