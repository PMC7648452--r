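test_that("GTF parsing keeps only basic protein-coding transcripts", {
  f <- tempfile(fileext = ".gtf")
  on.exit(unlink(f))
  write_mini_gtf(f)
  models <- parse_gtf(f)
  expect_length(models, 1L)
  tx <- models[["T1"]]
  expect_equal(tx$transcript_id, "T1")
  expect_equal(nrow(tx$exons), 2L)
  # 1-based inclusive GTF converted to 0-based half-open
  expect_equal(tx$exons$start, c(100L, 300L))
  expect_equal(tx$exons$end, c(200L, 400L))
  # excluded transcripts are recoverable by relaxing the filters
  all_models <- parse_gtf(f, protein_coding_only = FALSE, basic_only = FALSE)
  expect_setequal(names(all_models), c("T1", "T2", "T3"))
  expect_false(all_models[["T2"]]$is_protein_coding)
  expect_false(all_models[["T3"]]$is_gencode_basic)
})

test_that("malformed GTF input is rejected with diagnostics", {
  f <- tempfile(fileext = ".gtf")
  on.exit(unlink(f))
  writeLines(c(paste("c1\ttest\texon\t1\t10\t.\t+\t.",
                     'gene_id "G"; transcript_id "T"; transcript_biotype "protein_coding"; tag "basic";',
                     sep = "\t"),
               "bad line"), f)
  expect_error(parse_gtf(f), "line 2", class = "ks_parse_error")
  writeLines(paste("c1\ttest\tCDS\t10\t5\t.\t+\t0",
                   'gene_id "G"; transcript_id "T"; transcript_biotype "protein_coding"; tag "basic";',
                   sep = "\t"), f)
  expect_error(parse_gtf(f), class = "ks_parse_error")
  # CDS without exons is a model error
  writeLines(paste("c1\ttest\tCDS\t5\t10\t.\t+\t0",
                   'gene_id "G"; transcript_id "T"; transcript_biotype "protein_coding"; tag "basic";',
                   sep = "\t"), f)
  expect_error(parse_gtf(f), class = "ks_model_error")
})

test_that("spliced and CDS sequences respect order and strand", {
  g <- c(c1 = "AACGTTTGCAT")
  tx <- make_tx(rbind(c(2L, 5L), c(8L, 11L)))
  expect_equal(spliced_sequence(tx, g), "CGTCAT")
  txm <- make_tx(rbind(c(2L, 5L), c(8L, 11L)), strand = "-")
  expect_equal(spliced_sequence(txm, g), "ATGACG")
  single <- make_tx(rbind(c(2L, 9L)))
  expect_equal(spliced_sequence(single, g), unname(substr(g, 3, 9)))
  # CDS restriction
  tx2 <- make_tx(rbind(c(0L, 6L)), cds = rbind(c(2L, 5L)))
  expect_equal(cds_sequence(tx2, g), "CGT")
  expect_error(spliced_sequence(make_tx(rbind(c(0L, 50L))), g),
               class = "ks_coordinate_error")
  expect_error(spliced_sequence(make_tx(rbind(c(0L, 4L)), chrom = "nope"), g),
               class = "ks_coordinate_error")
})

test_that("translation uses the standard codon table with strict framing", {
  expect_equal(translate_cds("ATGAAATAG"), "MK")
  expect_error(translate_cds("ATGA"), class = "ks_frame_error")
  expect_error(translate_cds("ATGTAAAAATAA"), class = "ks_premature_stop")
  # enumerate all 64 codons: 61 sense, 3 stop, 20 distinct amino acids
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  cls <- vapply(codons, function(cd) {
    tryCatch(substr(translate_cds(paste0(cd, "TAA")), 1, 1),
             ks_premature_stop = function(e) "*")
  }, character(1))
  expect_length(codons, 64L)
  expect_equal(sum(cls != "*"), 61L)
  expect_equal(sum(cls == "*"), 3L)
  expect_setequal(names(which(cls == "*")), c("TAA", "TAG", "TGA"))
  expect_equal(sort(unique(cls[cls != "*"])), sort(aa_alphabet()$symbols))
})

test_that("junction derivation anchors donors, acceptors and exon joints", {
  tx <- make_tx(rbind(c(100L, 200L), c(300L, 400L)))
  j <- derive_junctions(tx, min_dist = 0)
  expect_equal(j$kind, c("donor", "acceptor", "exon_exon"))
  expect_equal(j$anchor, c(200L, 300L, NA))
  expect_equal(j$spliced_pos, rep(100L, 3))
  expect_equal(j$dist_transcript, rep(100L, 3))
  # junction 50 nt from the transcript start is filtered at min_dist 100
  near <- make_tx(rbind(c(0L, 50L), c(100L, 300L)))
  expect_equal(nrow(derive_junctions(near, min_dist = 100)), 0L)
  expect_equal(nrow(derive_junctions(near, min_dist = 50)), 3L)
  # single-exon transcripts yield no junctions
  expect_equal(nrow(derive_junctions(make_tx(rbind(c(0L, 99L))))), 0L)
  # minus strand: anchors flip to transcript orientation
  txm <- make_tx(rbind(c(100L, 200L), c(300L, 400L)), strand = "-")
  jm <- derive_junctions(txm, min_dist = 0)
  expect_equal(jm$anchor[jm$kind == "donor"], 299L)   # first intron base
  expect_equal(jm$anchor[jm$kind == "acceptor"], 199L)
  # CDS-end filtering uses spliced CDS coordinates
  tx3 <- make_tx(rbind(c(0L, 120L), c(200L, 320L), c(400L, 520L)))
  j3 <- derive_junctions(tx3, filter_kind = "cds_ends", min_dist = 121)
  expect_equal(nrow(j3), 0L)
  j3b <- derive_junctions(tx3, filter_kind = "cds_ends", min_dist = 120)
  expect_equal(nrow(j3b), 6L)
  expect_equal(unique(j3b$phase), 0L)
})

test_that("spliced offsets map to genomic locus keys across junctions", {
  tx <- make_tx(rbind(c(100L, 200L), c(300L, 400L)))
  expect_equal(map_to_locus(tx, 98L, 4L),
               data.frame(chrom = "c1", strand = "+", start = 198L, end = 302L))
  expect_equal(map_to_locus(tx, 0L, 3L),
               data.frame(chrom = "c1", strand = "+", start = 100L, end = 103L))
  txm <- make_tx(rbind(c(100L, 200L), c(300L, 400L)), strand = "-")
  expect_equal(map_to_locus(txm, 0L, 3L)$start, 397L)
  expect_equal(map_to_locus(txm, 0L, 3L)$end, 400L)
  # brute-force strand oracle: walk the posmap base by base
  pm <- rev(c(100:199, 300:399))
  for (o in c(0L, 50L, 98L, 150L)) {
    span <- pm[(o + 1):(o + 6)]
    got <- map_to_locus(txm, o, 6L)
    expect_equal(got$start, min(span))
    expect_equal(got$end, max(span) + 1L)
  }
  expect_error(map_to_locus(tx, 198L, 4L), class = "ks_coordinate_error")
  # junction anchors round-trip to the exon ends they straddle
  j <- derive_junctions(tx, min_dist = 0)
  sp <- j$spliced_pos[j$kind == "exon_exon"]
  expect_equal(map_to_locus(tx, sp, 1L)$start, 300L)
  expect_equal(map_to_locus(tx, sp - 1L, 1L)$end, 200L)
})

test_that("locus deduplication collapses shared exons deterministically", {
  occ <- data.frame(
    kmer = c("ACG", "ACG", "ACG", "TTT"),
    chrom = "c1", strand = "+",
    start = c(10L, 10L, 50L, 90L), end = c(13L, 13L, 53L, 93L),
    transcript_id = c("t2", "t1", "t1", "t1"))
  out <- dedup_kmers(occ)
  expect_equal(nrow(out), 3L)
  expect_equal(out$transcript_id[out$start == 10L], "t1")  # ordered retention
  # same key, different k-mer: warn, keep first
  occ2 <- data.frame(kmer = c("AAA", "CCC"), chrom = "c1", strand = "+",
                     start = 5L, end = 8L, transcript_id = c("t1", "t2"))
  expect_warning(out2 <- dedup_kmers(occ2), "collision")
  expect_equal(out2$kmer, "AAA")
})

test_that("coding k-mer tables are invariant to duplicated transcripts", {
  gen <- small_fixture()
  dup <- unclass(gen$models)
  for (tx in gen$models) {
    tx$transcript_id <- paste0(tx$transcript_id, "_dup")
    dup[[tx$transcript_id]] <- tx
  }
  dup <- structure(dup, class = "transcript_models")
  for (space in c("mrna", "aa")) {
    k <- if (space == "mrna") 5L else 2L
    a <- coding_kmer_table(gen$models, gen$genome, k, space)
    b <- coding_kmer_table(dup, gen$genome, k, space)
    expect_identical(a$counts, b$counts)
    expect_identical(a$total, b$total)
  }
  # and the correction actually removes shared-exon duplicates: totals are
  # below the uncorrected per-transcript sum
  per_tx <- sum(vapply(gen$models, function(tx) {
    nrow(extract_kmers(cds_sequence(tx, gen$genome), 5L))
  }, numeric(1)))
  expect_lt(coding_kmer_table(gen$models, gen$genome, 5L, "mrna")$total, per_tx)
})

test_that("generated fixtures round-trip through files byte-identically", {
  gen <- small_fixture()
  spec <- gen$spec
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  p1 <- write_fixture(spec, d1)
  p2 <- write_fixture(spec, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  models <- parse_gtf(p1$gtf)
  expect_length(models, length(gen$models))
  genome <- read_genome_fasta(p1$fasta)
  expect_identical(genome, gen$genome)
  peps <- read_peptide_fasta(p1$peptides)
  for (tx in models) {
    expect_identical(tx$exons, gen$models[[tx$transcript_id]]$exons)
    expect_identical(translate_cds(cds_sequence(tx, genome)),
                     unname(peps[tx$transcript_id]))
  }
  manifest <- jsonlite::read_json(p1$manifest)
  expect_equal(manifest$spec$seed, spec$seed)
  expect_equal(length(manifest$genes), nrow(gen$genes))
})
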