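Package: kmersurprisal
Title: k-mer Surprisal and Information Content of Genomes and Splice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free analysis of the information content of biological
    sequences. Builds genome-wide k-mer frequency tables over nucleotide and
    amino-acid alphabets and derives Shannon surprisal, entropy and redundancy
    statistics from them, including saturation diagnostics for choosing k.
    Parses Ensembl-dialect GTF annotation into strand-aware transcript models,
    derives donor, acceptor and exon-exon splice junctions, and computes
    junction-anchored mean-surprisal profiles in DNA, coding-mRNA and
    amino-acid space with a multiple-transcript genomic-locus correction.
    Includes dinucleotide composition analyses (CG-segregated k-mer spectra,
    phased codon usage, per-position motif information content) and a seeded
    synthetic genome + GTF generator with planted splice features for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
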