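test_that("a minus-strand occurrence is reported in motif orientation", {
  # plus strand carries CCATTAA at -21..-15, i.e. TTAATGG read on the minus
  # strand; the hit is reported start -15, end -21, strand -
  set.seed(101)
  prom <- random_seq(100)
  ch <- strsplit(prom, "")[[1]]
  ch[80:86] <- strsplit("CCATTAA", "")[[1]]  # offsets 80..86 = -21..-15
  prom <- paste(ch, collapse = "")
  lib <- motif_library("WUSATAg", "TTAATGG")
  hits <- scan_motifs(prom, lib, first_pos = -100L)
  h <- hits[hits$span_lo == -21L, ]
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, -15L)
  expect_identical(h$end, -21L)
  expect_identical(h$strand, "-")
  expect_identical(h$matched, "TTAATGG")
})

test_that("degenerate patterns report every (overlapping) occurrence", {
  lib <- motif_library("MYB1AT", "WAACCA")
  hits <- scan_motifs("AAACCATAACCA", lib, first_pos = 1L)
  plus <- hits[hits$strand == "+", ]
  expect_identical(sort(plus$matched), c("AAACCA", "TAACCA"))
  expect_identical(sort(plus$start), c(1L, 7L))
})

test_that("an invalid IUPAC character is rejected by name", {
  expect_error(motif_library("bad", "GAXAA"), "X")
  lib <- data.frame(motif_id = "bad", pattern = "GAXAA")
  expect_error(scan_motifs("ACGT", lib), "GAXAA")
})

test_that("minus-strand scanning equals plus-strand scanning of the
           reverse complement", {
  set.seed(102)
  pats <- c("TGTCA", "GAAAAA", "WAACCA", "YRYR", "CATGCATG", "MACCWAMC")
  for (trial in 1:6) {
    s <- random_seq(300)
    rc <- oracle_revcomp(s)
    for (p in pats) {
      lib <- motif_library("m", p)
      minus <- scan_motifs(s, lib, first_pos = 1L)
      minus <- minus[minus$strand == "-", ]
      plus_rc <- scan_motifs(rc, lib, first_pos = 1L)
      plus_rc <- plus_rc[plus_rc$strand == "+", ]
      # offsets map i..j on the minus strand to (n-j+1)..(n-i+1) on the rc
      expect_setequal(301L - minus$span_hi, plus_rc$span_lo)
      expect_identical(nrow(minus), nrow(plus_rc))
    }
  }
})

test_that("the scanner equals the expansion oracle for short patterns", {
  set.seed(103)
  pats <- c("TGTCA", "GAAAAA", "GATAA", "WAACCA", "GGATA", "CAACA",
            "TTATCC", "TTAATGG", "MACCWAMC", "NRYSWK")
  for (p in pats) {
    s <- random_seq(500, gc = 0.45)
    hits <- scan_motifs(s, motif_library("m", p), first_pos = 1L)
    want <- oracle_scan(s, p)
    got_plus <- hits[hits$strand == "+", c("span_lo", "span_hi")]
    want_plus <- want[want$strand == 1, c("lo", "hi")]
    expect_setequal(paste(got_plus$span_lo, got_plus$span_hi),
                    paste(want_plus$lo, want_plus$hi))
    got_minus <- hits[hits$strand == "-", c("span_lo", "span_hi")]
    want_minus <- want[want$strand == -1, c("lo", "hi")]
    expect_setequal(paste(got_minus$span_lo, got_minus$span_hi),
                    paste(want_minus$lo, want_minus$hi))
  }
})

test_that("every published promoter occurrence is recovered from the
           planted fixture", {
  for (gene in c("GSL1", "GSL2")) {
    fx <- gsl_promoter_fixture(gene, seed = 2)
    hits <- scan_motifs(fx, gsl_motif_library(gene))
    printed <- gsl_motif_hits(gene)
    key <- function(d) paste(d$motif_id, d$start, d$end, d$strand)
    expect_true(all(key(printed) %in% key(hits)))
    # strand convention: minus-strand rows have start > end
    expect_true(all(hits$start[hits$strand == "-"] >
                      hits$end[hits$strand == "-"]))
    expect_true(all(hits$start[hits$strand == "+"] <
                      hits$end[hits$strand == "+"]))
    # no hit fails its own pattern check
    pats <- gsl_motif_library(gene)
    for (i in seq_len(nrow(hits))) {
      p <- pats$pattern[pats$motif_id == hits$motif_id[i]][1]
      expect_true(hits$matched[i] %in% oracle_expand_pattern(p))
    }
  }
})

test_that("TSS prediction ranks a TATA-anchored YR dimer first", {
  # all-purine background: the only YR dimer is the planted one 33 nt
  # upstream of the ATG, with a TATA element ending 27 nt further upstream
  ch <- rep("G", 130)
  ch[120:122] <- c("A", "T", "G")        # ATG at offset 120 (33 nt 5'UTR)
  ch[86] <- "T"                          # -1 pyrimidine; +1 = offset 87 (G)
  ch[55:60] <- c("T", "A", "T", "A", "A", "A")  # TATAWA ending at 87 - 27
  cand <- predict_tss(paste(ch, collapse = ""), atg_offset = 120L,
                      window = 60L)
  expect_identical(cand$tss_offset[1], 87L)
  expect_identical(cand$upstream_of_atg[1], 33L)  # ATG begins at +34
  expect_true(cand$has_tata[1])
})

test_that("a window without pyrimidine-purine dimers has no candidates", {
  cand <- predict_tss(strrep("G", 80), atg_offset = 70L, window = 40L)
  expect_identical(nrow(cand), 0L)
})

test_that("TSS candidates equal the brute-force dimer enumeration", {
  set.seed(104)
  for (trial in 1:8) {
    s <- random_seq(200)
    ch <- strsplit(s, "")[[1]]
    cand <- predict_tss(s, atg_offset = 180L, window = 100L)
    want <- Filter(function(t) ch[t - 1] %in% c("C", "T") &&
                     ch[t] %in% c("A", "G"), 80:179)
    expect_setequal(cand$tss_offset, want)
  }
})

test_that("planted core elements are recovered at their coordinates", {
  m <- build_reference(gsl1_model_spec(seed = 5))
  ce <- find_core_elements(m$sequence, m$tss_index)
  expect_identical(ce$tata, c(-32L, -27L))
  expect_identical(ce$y_patch, c(-26L, -20L))
  expect_identical(ce$caat, c(-48L, -44L))
  expect_identical(ce$caat_status, "canonical")
})

test_that("a near-match CAAT-box is flagged hypothetical", {
  m <- build_reference(gsl2_model_spec(seed = 5))
  ce <- find_core_elements(m$sequence, m$tss_index)
  expect_identical(ce$caat, c(-65L, -61L))
  expect_identical(ce$caat_status, "hypothetical")
})

test_that("absent elements and short sequences are handled", {
  s <- strrep("A", 200)  # purine-only: no pyrimidine run, no TATA end match?
  ce <- find_core_elements(s, tss_offset = 150L)
  expect_null(ce$y_patch)
  expect_null(ce$caat)
  expect_error(find_core_elements(strrep("A", 100), tss_offset = 40L),
               "70 nt")
})

test_that("motif disruption requires footprint overlap with the hit span", {
  hits <- data.frame(motif_id = "GT1GMSCAM4", start = -826L, end = -821L,
                     strand = "+", matched = "GAAAAA",
                     span_lo = -826L, span_hi = -821L)
  snp_in <- data.frame(gene_id = "g", position = -824L, kind = "SNP",
                       ref = "A", alt = "G", length = 1L, carriers = "x")
  snp_out <- data.frame(gene_id = "g", position = -827L, kind = "SNP",
                        ref = "A", alt = "G", length = 1L, carriers = "x")
  d <- detect_disruptions(hits, list(C = snp_in, K = snp_out))
  expect_identical(nrow(d), 1L)
  expect_identical(d$genotype, "C")
  expect_identical(d$disruption_kind, "SNP")
  # a deletion reaching into the span from outside disrupts too
  del <- data.frame(gene_id = "g", position = -828L, kind = "indel",
                    ref = "ACGT", alt = "-", length = 4L, carriers = "x")
  d2 <- detect_disruptions(hits, list(V = del))
  expect_identical(d2$disruption_kind, "indel")
})

test_that("disruption detection equals an all-pairs interval oracle", {
  set.seed(105)
  for (trial in 1:6) {
    n_hits <- sample(4:10, 1)
    lo <- sort(sample(-400:-20, n_hits))
    hits <- data.frame(motif_id = paste0("m", seq_len(n_hits)),
                       start = lo, end = lo + 5L, strand = "+",
                       matched = "NNNNNN", span_lo = lo, span_hi = lo + 5L)
    gv <- list()
    for (g in c("geno1", "geno2")) {
      nv <- sample(3:8, 1)
      pos <- sample(-400:-10, nv)
      kind <- sample(c("SNP", "indel"), nv, replace = TRUE)
      len <- ifelse(kind == "SNP", 1L, sample(1:6, nv, replace = TRUE))
      gv[[g]] <- data.frame(gene_id = "g", position = pos, kind = kind,
                            ref = ifelse(kind == "SNP", "A", "ACGT"),
                            alt = ifelse(kind == "SNP", "G", "-"),
                            length = len, carriers = g)
    }
    d <- detect_disruptions(hits, gv)
    # brute force over all (hit, genotype, variant) triples
    want <- 0L
    for (g in names(gv)) for (i in seq_len(n_hits)) {
      v <- gv[[g]]
      f_lo <- v$position
      f_hi <- ifelse(v$kind == "indel", v$position + v$length - 1L,
                     v$position)
      if (any(f_lo <= hits$span_hi[i] & f_hi >= hits$span_lo[i]))
        want <- want + 1L
    }
    expect_identical(nrow(d), want)
  }
})
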