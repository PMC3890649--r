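Package: polyhap
Title: Haplotype Variation, Promoter Motifs and Allele Dosage in
    Autopolyploid Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A toolkit for gene-level conservation and regulation analysis
    in autopolyploids such as cultivated potato.  Provides a synthetic-data
    generator for gene models, tetraploid haplotype sets and short reads;
    haplotype-versus-reference variant discovery via affine-gap global
    alignment; pileup-based SNP calling with base-quality, read-support and
    unique-mapping filters; per-feature SNP/indel density accounting
    (nucleotides per SNP); cDNA-guided exon/intron structure inference;
    degenerate IUPAC promoter-motif scanning on both strands with
    allelic-disruption detection; transcription start site and core
    promoter element prediction; and maximum-likelihood allele dosage
    estimation from clone counts under a multinomial model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
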