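---
title: "polyhap: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyhap: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhap)
```

`polyhap` analyses allele-level variation and promoter regulation of genes
in autopolyploids, and ships a synthetic-data generator so that every stage
of the pipeline is testable without external downloads. This vignette
documents the underlying models, the numerical conventions, and the design
choices that were genuinely open, in enough detail that a maintainer can
predict the package's behaviour at edge cases.

## Coordinate system

All user-facing coordinates are anchored at the transcription start site
(TSS): the first transcribed base is +1, the base immediately upstream is
−1, and **there is no position 0**. This matches how plant promoter
annotations are conventionally printed. Internally every computation uses
plain 1-based array offsets; `pos_to_offset()` / `offset_to_pos()` are the
only crossing points, and they are bijective and order preserving.
Sorting TSS-anchored coordinates numerically is safe because the missing
zero does not disturb the order.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and are not tuned per analysis.

**Gene models.** `build_reference()` draws an i.i.d. background sequence
at a configurable GC fraction (default 0.5, a typical plant-genome
magnitude) and overwrites fixed features onto it: ATG at the first coding
exon, a stop codon at the end of the last, GT/AG dinucleotides at intron
boundaries, a pyrimidine–purine dimer across the TSS, planted promoter
motifs at declared coordinates, and core promoter elements. The two
presets mirror a well-studied pair of tetraploid potato genes:
`gsl1_model_spec()` (1960 nt promoter, 33 nt 5'UTR, exons of 82 and 185 nt
around a 504 nt intron, 205 nt 3'UTR) and `gsl2_model_spec()` (590 nt
promoter, 38 nt 5'UTR, exons of 87/46/182 nt, introns of 249/163 nt,
302 nt 3'UTR). When core elements are planted, the window −80..−10 is
first filled with purines so that the planted TATA-box, pyrimidine patch
and CAAT-box are the unique matches in their search windows; this is a
deliberate low-complexity patch that makes recovery tests exact, and it is
the one place where the background is not i.i.d.

**Haplotypes.** `spawn_haplotypes()` plants exactly the requested number
of SNPs and indels per annotated region. Haplotype `hap0` always equals
the reference; every variant is assigned to a uniformly random non-empty
subset of the mutated haplotypes, because no per-haplotype sharing
structure is established for these genes — this is the one place where the
generator invents structure rather than emulating a reported condition.
Indel lengths are uniform on a configurable range (default 1–7 nt; a
reported range, with no distribution stated, so uniform is the neutral
choice). SNP/indel placement uses a stars-and-bars construction that
guarantees success whenever the region has capacity, with two safeguards:

* footprints are separated by at least `min_sep` (default 8 nt) and kept
  `margin` (default 8 nt) away from region boundaries, so that small
  alignment-induced position shifts cannot move a variant across a region
  boundary or fuse two events;
* after building the haplotypes, the generator *verifies* that
  alignment-based re-discovery (`diff_haplotype()` →
  `merge_variant_tables()` → `summarize_regions()`) reproduces the
  requested per-region counts exactly, and re-draws the placement if not
  (deterministically, from the same seed stream).

The verification step exists because spacing alone cannot make planting
unambiguous at realistic densities: with 40 variants in a 504 nt intron, a
deletion and an insertion that land near each other can be re-expressed by
an *optimal* affine-gap alignment as substitutions plus a smaller net gap
whenever the shifted bases coincidentally match — roughly one attempt in
five produces such a configuration somewhere in a full genotype. Rather
than weakening the planting densities, the generator enforces its own
contract: the union of planted variants, as recovered by the package's own
variant discovery, equals the request exactly.

**Reads.** `simulate_reads()` emits single-end, pre-placed reads (there is
no mapper; placements are ground truth). Reads per haplotype are
proportional to its copy number. Two placement modes exist: `"tiled"`
(default) spaces read starts evenly so that every interior position
receives its expected depth deterministically — with 12× coverage of a
tetraploid, a simplex haplotype contributes exactly 3–4 overlapping reads
at every position more than a read length from the sequence ends — and
`"random"` draws uniform starts for binomial-noise behaviour. Base errors
are i.i.d. per base at a configured rate, substituting a uniformly chosen
other base; phred qualities are normal (mean 35, sd 3, clamped to 2..41)
and independent of the error process. The non-unique flag is assigned at
random at a configured rate, not from sequence repetitiveness: downstream
code only consumes the flag. None of this models empirical error spectra,
paired-end inserts, or mappability — so passing tests demonstrate the
*logic* of the caller and accounting, not robustness to real instrument
artefacts.

**Clones.** `sample_clones()` is a multinomial draw with probabilities
`dosage / ploidy`, the generative counterpart of the dosage estimator.

## Variant discovery

`align_global()` performs end-to-end pairwise alignment with affine gap
penalties; a gap of length L costs `gap_open + L * gap_extend`. Defaults
are match 2, mismatch −3, open 5, extend 2: gaps are expensive enough that
isolated planted variants are recovered exactly, and the suite pins
correctness against an independent dynamic-programming oracle and, at tiny
sizes, exhaustive enumeration of all alignments. `diff_haplotype()` turns
the alignment into events: one SNP per mismatch column, one indel per
*maximal* gap run (a 7 nt deletion is one event of length 7, matching how
allele differences are conventionally counted). An insertion is anchored
at the reference base before which it sits; a deletion at its first
removed base. `merge_variant_tables()` unions carriers of identical
(position, kind, ref, alt) events and rejects conflicting reference
alleles.

## Pileup SNP calling

The caller encodes three filters: only uniquely mapped reads (flag-based),
base quality **strictly above** phred 15 (a reading of "above" as strict;
an observation at exactly 15 is excluded, and the threshold is
configurable), and at least three passing reads supporting the alternative
base. There is no default minimum alternative-allele fraction: a simplex
allele in a tetraploid is expected in only ~25% of reads, so a fraction
cut-off would be systematically biased against exactly the alleles of
interest; the parameter exists (`min_alt_fraction`) for stricter use.
Calls are per (position, alternative base). The caller is monotone:
adding a passing alternative observation never removes a call, and raising
the support threshold never adds one. Indels are out of scope in pileup
mode — the simulator emits SNP-only placements, and the indel inventory of
the pipeline comes from haplotype comparison.

## Feature-wise conservation accounting

`summarize_regions()` partitions a variant table over a region annotation;
an indel belongs to the region of its first affected reference base (the
tie-break for boundary-spanning indels, which is otherwise arbitrary).
The conservation statistic is nucleotides-per-SNP = size / SNP count,
rounded to one decimal **half away from zero**; `aggregate_frequency()`
pools selected regions (sum of sizes over sum of counts) and rounds to the
nearest integer the same way. Half-away-from-zero is forced by the
printed reference values this accounting mirrors (a pooled 315/6 = 52.5
prints as 53, and 590/12 = 49.1\overline{6} as 49.2); base R's `round()`
rounds half to even and would print 52. A region with zero SNPs has an
undefined density, carried as `NA` and rendered `-` in report files.
Promoter bins count backwards from −1 in `promoter_bin`-sized steps, so
the most-upstream bin may be short (e.g. 460 nt of a 1960 nt promoter at
bin size 500); `promoter_bin = Inf` keeps one promoter row.

## Gene structure inference

`infer_gene_structure()` places a cDNA onto its genomic sequence as an
ordered exact concatenation of exon blocks whose skipped segments are
introns of at least `min_intron` nt starting GT and ending AG. The search
is a depth-first enumeration with failure memoisation that prefers opening
an intron over extending an exon, which yields the *leftmost* placement
(earliest first exon, then lexicographically earliest donors/acceptors) —
a tie-break chosen purely for determinism, since nothing in the data
distinguishes equally valid placements. `min_intron` defaults to 50 nt;
smaller values admit spurious GT..AG micro-introns in random sequence
(in a 500 nt i.i.d. background a valid ≥10 nt intron arises by chance in a
few percent of draws, a ≥50 nt one essentially never, while true plant
introns below 50 nt are rare). Mismatch-tolerant spliced alignment and
alternative isoforms are out of scope.

## Promoter analysis

`scan_motifs()` does exact degenerate matching: an IUPAC letter matches
its base set, with no mismatches and no position-weight scoring — the
motif libraries shipped with the package are literal degenerate patterns,
and matrix scores would not be reproducible from patterns alone. Both
strands are scanned and overlapping occurrences all reported. Coordinates
follow the motif's own 5'→3' orientation: a minus-strand hit is reported
with `start` at its downstream-most TSS-anchored coordinate, so
`start > end` — the convention used in printed promoter tables — while the
normalized `span_lo`/`span_hi` pair serves interval logic.
`detect_disruptions()` intersects variant footprints (a SNP's position, a
deletion's removed bases, an insertion's anchor base) with hit spans, per
genotype.

`predict_tss()` implements the YR dimer rule — plant transcription tends
to start on a purine preceded by a pyrimidine — and returns *ranked
candidates* rather than one forced answer: candidates with a TATA element
(`TATAWA`) ending 25–35 nt upstream rank first, nearer-to-ATG breaks
ties. The ranking rule is a package decision; only the dimer rule itself
and typical TATA spacing are established conventions. `find_core_elements()`
searches fixed windows upstream of the TSS — TATA-box (`TATAWA`, −45..−20,
downstream-most match wins), pyrimidine patch (longest run of ≥5
pyrimidines in −60..−10, ties downstream), CAAT-box (exact `CCAAT` in
−80..−30, else the best single-mismatch match flagged `"hypothetical"`).
The windows and operationalizations are calibrated to reproduce standard
annotations of the two preset genes and are all configurable; on arbitrary
promoters they should be read as a screening heuristic, not a predictor.

## Allele dosage

Sequencing *n* clones of a polyploid locus is modelled as a multinomial
draw in which each clone carries allele *i* with probability
`dosage_i / ploidy`. `estimate_dosage()` enumerates every integer dosage
vector with entries ≥ `min_copies` summing to the ploidy and maximises
`sum_i counts_i * log(dosage_i / ploidy)` (with `0 * log(0) = 0`; an
unobserved allele at dosage 0 is fine, an observed allele at dosage 0 has
likelihood −∞). `min_copies` defaults to 1 — an allele that was cloned
and sequenced exists at least once — and can be set to 0. There is no
prior and no model averaging; instead every candidate vector is reported
with its log-likelihood and likelihood ratio to the maximum, and ties set
`ml_unique = FALSE` rather than being broken silently. For clone counts
of 15:1 at ploidy 4 the 3+1 configuration beats 2+2 by a likelihood ratio
of ~219; even the seemingly ambiguous 10:2 favours 3+1. Simulation in the
test suite confirms the estimator is consistent: accuracy against the true
dosage is non-decreasing in clone count and exceeds 95% by 100 clones for
a two-allele tetraploid.

## Problem sizes and determinism

The test suite and the acceptance script run at the scale the analysis is
designed for: full gene models of ~1.7–3 kb, four haplotypes, 12×
simulated coverage with 100 nt reads, 20 replicate seeds for caller
recovery/false-positive rates, 1000 replicates per depth for dosage
consistency, and exhaustive oracles at reduced sizes (alignments up to
8 nt against an independent DP, all splice placements on ≤200 nt
instances, full dosage sweeps for all two-allele counts up to n = 20).
Every stochastic step takes an explicit integer seed and is byte-stable
given it; the acceptance script derives all of its seeds from a single
`--seed` argument.

## Known limitations

* Variant discovery assumes two haploid sequences per comparison; there is
  no multi-sequence progressive alignment.
* Pileup mode is SNP-only and trusts read placements; there is no
  realignment, no mapping-quality model beyond the unique flag, and no
  error-spectrum realism in the simulator.
* The motif scanner cannot rank partial matches (no PWM scores), so motif
  inventories are as complete as their pattern libraries and no more.
* Core-element and TSS heuristics are calibrated on the two shipped
  presets; their windows are defaults, not biology-free constants.
* The expression comparison consumes externally computed FPKM tables; the
  package does not quantify expression from raw reads.
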