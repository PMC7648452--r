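# Shared fixtures and independent oracles for the test suite.

# Naive substring-scan k-mer counter, independent of the encoded counting
# path: enumerate every window, drop windows with foreign symbols, tabulate.
oracle_count_kmers <- function(sequences, k, alphabet = nt_alphabet(),
                               both_strands = FALSE) {
  seqs <- toupper(sequences)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    seqs <- c(seqs, rc)
  }
  bad <- paste0("[^", paste(alphabet$symbols, collapse = ""), "]")
  subs <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }))
  subs <- subs[!grepl(bad, subs)]
  tab <- table(subs)
  list(counts = stats::setNames(as.numeric(tab), names(tab)),
       total = length(subs))
}

# Random nucleotide sequence with occasional Ns (exercises window skipping).
random_dna <- function(n, n_prob = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}

# Hand-built transcript model (0-based half-open intervals, transcript order).
make_tx <- function(exons, strand = "+", chrom = "c1", cds = exons,
                    id = "tx1", gene = "g1") {
  ex <- data.frame(start = exons[, 1], end = exons[, 2])
  cd <- data.frame(start = cds[, 1], end = cds[, 2])
  if (strand == "-") {
    ex <- ex[order(ex$start, decreasing = TRUE), , drop = FALSE]
    cd <- cd[order(cd$start, decreasing = TRUE), , drop = FALSE]
  } else {
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
  }
  rownames(ex) <- rownames(cd) <- NULL
  structure(list(transcript_id = id, gene_id = gene, chrom = chrom,
                 strand = strand, exons = ex, cds = cd,
                 is_protein_coding = TRUE, is_gencode_basic = TRUE),
            class = "transcript_model")
}

# A small synthetic genome, generated once per test run and reused.
.fixture_env <- new.env(parent = emptyenv())
small_fixture <- function() {
  if (is.null(.fixture_env$gen)) {
    spec <- synthetic_genome_spec(seed = 421L,
                                  chrom_lengths = c(80000L, 50000L),
                                  n_genes = 8L)
    .fixture_env$spec <- spec
    .fixture_env$gen <- generate_synthetic_genome(spec)
  }
  .fixture_env$gen
}

# Minimal Ensembl-dialect GTF text for parser tests.
write_mini_gtf <- function(path) {
  lines <- c(
    "#!genome-build test",
    paste("c1\ttest\tgene\t101\t400\t.\t+\t.",
          'gene_id "G1";', sep = "\t"),
    paste("c1\ttest\ttranscript\t101\t400\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic";',
          sep = "\t"),
    paste("c1\ttest\texon\t101\t200\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic"; exon_number "1";',
          sep = "\t"),
    paste("c1\ttest\texon\t301\t400\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic"; exon_number "2";',
          sep = "\t"),
    paste("c1\ttest\tCDS\t101\t200\t.\t+\t0",
          'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic";',
          sep = "\t"),
    paste("c1\ttest\tCDS\t301\t400\t.\t+\t2",
          'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic";',
          sep = "\t"),
    # non-coding transcript: must be excluded
    paste("c1\ttest\texon\t501\t600\t.\t+\t.",
          'gene_id "G2"; transcript_id "T2"; transcript_biotype "lncRNA"; tag "basic";',
          sep = "\t"),
    # protein coding but not GENCODE basic: must be excluded
    paste("c1\ttest\texon\t701\t800\t.\t+\t.",
          'gene_id "G3"; transcript_id "T3"; transcript_biotype "protein_coding";',
          sep = "\t"))
  writeLines(lines, path)
  path
}
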