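test_that("build_reference produces the requested span deterministically", {
  m1 <- build_reference(gsl1_model_spec(seed = 7))
  m2 <- build_reference(gsl1_model_spec(seed = 7))
  m3 <- build_reference(gsl1_model_spec(seed = 8))
  expect_identical(nchar(m1$sequence), 1960L + 33L + 82L + 504L + 185L + 205L)
  expect_identical(m1$sequence, m2$sequence)
  expect_false(identical(m1$sequence, m3$sequence))
  expect_identical(m1$atg_pos, 34L)
  # introns begin GT and end AG
  intr <- m1$regions[m1$regions$label == "intron_1", ]
  o <- pos_to_offset(c(intr$start, intr$end), m1$tss_index)
  expect_identical(substr(m1$sequence, o[1], o[1] + 1L), "GT")
  expect_identical(substr(m1$sequence, o[2] - 1L, o[2]), "AG")
})

test_that("planted motifs appear at their declared coordinates", {
  spec <- gene_model_spec(
    regions = data.frame(label = c("promoter", "utr5", "exon_1", "utr3"),
                         length = c(1800L, 30L, 90L, 60L)),
    planted_motifs = data.frame(motif_id = "GT1GMSCAM4", seq = "GAAAAA",
                                start = -1678L, end = -1673L, strand = "+"),
    seed = 3L)
  m <- build_reference(spec)
  o <- pos_to_offset(c(-1678L, -1673L), m$tss_index)
  expect_identical(substr(m$sequence, o[1], o[2]), "GAAAAA")
  # scanning with an empty library yields no hits
  empty <- motif_library(character(0), character(0))
  expect_identical(nrow(scan_motifs(m, empty)), 0L)
})

test_that("overlapping planted features are rejected with the pair named", {
  expect_error(
    gene_model_spec(
      regions = data.frame(label = c("promoter", "utr5"),
                           length = c(500L, 30L)),
      planted_motifs = data.frame(motif_id = c("m1", "m2"),
                                  seq = c("GAAAAA", "TGTCA"),
                                  start = c(-100L, -97L),
                                  end = c(-95L, -93L),
                                  strand = c("+", "+"))),
    "overlap.*m1.*m2")
})

test_that("spawn_haplotypes plants exactly the requested counts per region", {
  m <- build_reference(gsl1_model_spec(seed = 2))
  reg <- annotate_regions(m, promoter_bin = 500)
  sp <- spawn_haplotypes(m, gsl1_region_counts(), regions = reg, seed = 5)
  tr <- sp$truth
  in_region <- function(v, r) r$start <= v & v <= r$end
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    want <- gsl1_region_counts()[gsl1_region_counts()$label == r$label, ]
    expect_identical(sum(tr$kind == "SNP" & in_region(tr$position, r)),
                     want$n_snps)
    expect_identical(sum(tr$kind == "indel" & in_region(tr$position, r)),
                     want$n_indels)
  }
  # every variant has at least one carrier; hap0 is unmutated
  expect_true(all(nzchar(tr$carriers)))
  expect_identical(sp$haplotypes[["hap0"]], m$sequence)
})

test_that("all-zero counts give haplotypes identical to the reference", {
  m <- build_reference(gsl1_model_spec(seed = 2))
  zero <- gsl1_region_counts()
  zero$n_snps <- 0L; zero$n_indels <- 0L
  sp <- spawn_haplotypes(m, zero, regions = annotate_regions(m, 500), seed = 5)
  expect_identical(nrow(sp$truth), 0L)
  expect_true(all(sp$haplotypes == m$sequence))
})

test_that("SNP-only truth equals the union of independent per-haplotype diffs", {
  spec <- gene_model_spec(
    regions = data.frame(label = c("promoter", "utr5"),
                         length = c(500L, 40L)), seed = 11L)
  m <- build_reference(spec)
  counts <- data.frame(label = "promoter", n_snps = 5L, n_indels = 0L)
  sp <- spawn_haplotypes(m, counts, regions = m$regions, seed = 13)
  # independent recovery: per-position character comparison, no alignment
  union_pos <- sort(unique(unlist(lapply(sp$haplotypes[-1], function(h) {
    hc <- strsplit(h, "")[[1]]
    rc <- strsplit(m$sequence, "")[[1]]
    offset_to_pos(which(hc != rc), m$tss_index)
  }))))
  expect_identical(union_pos, sort(sp$truth$position))
  expect_identical(length(union_pos), 5L)
})

test_that("haplotypes equal the reference with the truth applied", {
  m <- build_reference(gsl2_model_spec(seed = 6))
  sp <- spawn_haplotypes(m, gsl2_region_counts(),
                         regions = annotate_regions(m, Inf), seed = 21)
  for (h in names(sp$haplotypes)[-1]) {
    mine <- sp$truth[vapply(strsplit(sp$truth$carriers, ","),
                            function(cs) h %in% cs, logical(1)), ]
    expect_identical(sp$haplotypes[[h]],
                     oracle_apply_variants(m$sequence, mine, m$tss_index))
  }
})

test_that("a region too small for its requested count is rejected by name", {
  m <- build_reference(gene_model_spec(
    regions = data.frame(label = c("promoter", "utr5"),
                         length = c(60L, 30L)), seed = 1L))
  counts <- data.frame(label = "promoter", n_snps = 20L, n_indels = 5L)
  expect_error(spawn_haplotypes(m, counts, regions = m$regions, seed = 1),
               "promoter")
})

test_that("read counts follow the coverage arithmetic", {
  spec <- gene_model_spec(
    regions = data.frame(label = c("promoter", "utr5"),
                         length = c(900L, 100L)), seed = 4L)
  m <- build_reference(spec)
  haps <- c(hap0 = m$sequence)
  # coverage 12x over 1000 nt with 100 nt reads ~ 120 reads
  for (mode in c("tiled", "random")) {
    reads <- simulate_reads(m, haps, dosage = 1L,
                            cfg = read_sim_config(placement = mode, seed = 2))
    expect_gt(nrow(reads), 105)
    expect_lt(nrow(reads), 135)
  }
})

test_that("haplotype representation is proportional to dosage", {
  spec <- gene_model_spec(
    regions = data.frame(label = c("promoter", "utr5"),
                         length = c(900L, 100L)), seed = 4L)
  m <- build_reference(spec)
  haps <- c(hap0 = m$sequence, hap1 = m$sequence)
  reads <- simulate_reads(m, haps, dosage = c(3L, 1L),
                          cfg = read_sim_config(seed = 3))
  expect_equal(mean(reads$hap == "hap0"), 0.75, tolerance = 0.01)
  # random placement: binomial error over seeds
  fr <- vapply(1:10, function(s) {
    r <- simulate_reads(m, haps, dosage = c(3L, 1L),
                        cfg = read_sim_config(placement = "random", seed = s))
    mean(r$hap == "hap0")
  }, numeric(1))
  expect_equal(mean(fr), 0.75, tolerance = 0.05)
})

test_that("the non-unique flag is assigned at the configured rate", {
  spec <- gene_model_spec(
    regions = data.frame(label = c("promoter", "utr5"),
                         length = c(2900L, 100L)), seed = 4L)
  m <- build_reference(spec)
  reads <- simulate_reads(m, c(hap0 = m$sequence), dosage = 1L,
                          cfg = read_sim_config(nonunique_fraction = 0.2,
                                                seed = 5))
  expect_equal(mean(reads$unique_flag == 0L), 0.2, tolerance = 0.06)
})

test_that("degenerate simulator inputs are rejected", {
  m <- build_reference(gsl1_model_spec(seed = 1))
  expect_error(simulate_reads(m, c(hap0 = m$sequence), dosage = 0L), "ploidy")
  expect_error(simulate_reads(m, c(hap0 = substr(m$sequence, 1, 100)),
                              dosage = 1L), "SNP-only")
  expect_error(read_sim_config(base_error_rate = 1.2), "base_error_rate")
  expect_error(read_sim_config(coverage = 0), "coverage")
})

test_that("clone sampling is multinomial in the dosage proportions", {
  expect_identical(sample_clones(c(4, 0), 16, seed = 1),
                   c(allele1 = 16L, allele2 = 0L))
  expect_identical(sum(sample_clones(c(2, 2), 12, seed = 2)), 12L)
  expect_error(sample_clones(c(-1, 2), 10), ">= 0")
  expect_error(sample_clones(c(0, 0), 10), ">= 1")
  # law of large numbers: mean count of the 3-copy allele ~ 12 of 16
  means <- vapply(1:2000, function(s)
    sample_clones(c(3, 1), 16, seed = s)[[1]], numeric(1))
  expect_equal(mean(means), 12, tolerance = 0.1)
})

test_that("simulation is byte-identical for a fixed seed", {
  m <- build_reference(gsl1_model_spec(seed = 9))
  sp1 <- spawn_haplotypes(m, gsl1_region_counts(),
                          regions = annotate_regions(m, 500), seed = 31)
  sp2 <- spawn_haplotypes(m, gsl1_region_counts(),
                          regions = annotate_regions(m, 500), seed = 31)
  expect_identical(sp1, sp2)
  r1 <- simulate_reads(m, c(hap0 = m$sequence), 1L, read_sim_config(seed = 8))
  r2 <- simulate_reads(m, c(hap0 = m$sequence), 1L, read_sim_config(seed = 8))
  expect_identical(r1, r2)
})
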