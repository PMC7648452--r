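test_that("junction windows read genomic context on the transcript strand", {
  g <- c(chr = paste0(strrep("A", 196), "ACGTGTAA", strrep("C", 100)))
  jx <- data.frame(kind = "donor", chrom = "chr", strand = "+", anchor = 200L,
                   spliced_pos = NA, cds_pos = NA, phase = NA,
                   transcript_id = "t", dist_transcript = 999L, dist_cds = NA)
  w <- junction_windows(jx, genome = g, upstream = 4, downstream = 4)
  expect_equal(as.character(w), "ACGTGTAA")
  expect_false(attr(w, "truncated"))

  # minus strand: offset i is genomic position anchor - i, complemented
  gm <- c(chr = "AAAACCGTGTTT")
  jm <- jx; jm$chrom <- "chr"; jm$strand <- "-"; jm$anchor <- 5L
  wm <- junction_windows(jm, genome = gm, upstream = 3, downstream = 3)
  chars <- strsplit(gm[["chr"]], NULL)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- paste(comp[chars[5L - (-3:2) + 1L]], collapse = "")
  expect_equal(as.character(wm), oracle)

  # windows overrunning the contig are padded and flagged, not dropped
  jt <- jx; jt$anchor <- 2L
  wt <- junction_windows(jt, genome = g, upstream = 4, downstream = 4)
  expect_true(attr(wt, "truncated"))
  expect_equal(substr(as.character(wt), 1, 2), "..")
  expect_equal(nchar(as.character(wt)), 8L)

  # spliced windows come from per-transcript sequences
  js <- data.frame(kind = "exon_exon", chrom = "chr", strand = "+",
                   anchor = NA, spliced_pos = 4L, cds_pos = 4L, phase = 1L,
                   transcript_id = "t1", dist_transcript = 99L, dist_cds = 99L)
  ws <- junction_windows(js, seqs = c(t1 = "AAACGTTT"), upstream = 2,
                         downstream = 2)
  expect_equal(as.character(ws), "ACGT")
})

test_that("profile aggregation matches hand-computed per-offset means", {
  tab <- kmer_count_table(c(AA = 4, AC = 2, CA = 1, CC = 1))
  st <- surprisal_table(tab)
  jx <- data.frame(kind = "exon_exon", chrom = "c", strand = "+", anchor = NA,
                   spliced_pos = c(2L, 2L), cds_pos = c(2L, 2L), phase = 0L,
                   transcript_id = c("u", "v"),
                   dist_transcript = 9L, dist_cds = 9L)
  w <- junction_windows(jx, seqs = c(u = "AAAA", v = "ACCA"), upstream = 2,
                        downstream = 2)
  p <- profile_surprisal(w, st)
  s <- function(km) kmer_surprisal(tab, km)
  expect_equal(p$offsets, c(-2L, -1L, 0L))
  expect_equal(p$stats$mean_surprisal,
               c(mean(c(s("AA"), s("AC"))),
                 mean(c(s("AA"), s("CC"))),
                 mean(c(s("AA"), s("CA")))))
  expect_equal(p$stats$n, rep(2L, 3))
  # identical windows: sd exactly 0 at every offset
  w2 <- junction_windows(jx, seqs = c(u = "ACCA", v = "ACCA"), upstream = 2,
                         downstream = 2)
  p2 <- profile_surprisal(w2, st)
  expect_equal(p2$stats$sd, rep(0, 3))
  # permuting junctions leaves the profile bit-identical
  wp <- junction_windows(jx[2:1, ], seqs = c(u = "AAAA", v = "ACCA"),
                         upstream = 2, downstream = 2)
  p3 <- profile_surprisal(wp, st)
  expect_identical(p3$stats[, -1], p$stats[, -1])
  # means stay within the table's surprisal range
  rng <- range(-log2(tab$counts / tab$total))
  ok <- !is.na(p$stats$mean_surprisal)
  expect_true(all(p$stats$mean_surprisal[ok] >= rng[1] - 1e-12 &
                    p$stats$mean_surprisal[ok] <= rng[2] + 1e-12))
})

test_that("nullomer and padded k-mers are excluded per offset, not per junction", {
  tab <- kmer_count_table(c(AC = 1, CG = 1))
  st <- surprisal_table(tab)
  jx <- data.frame(kind = "exon_exon", chrom = "c", strand = "+", anchor = NA,
                   spliced_pos = 2L, cds_pos = 2L, phase = 0L,
                   transcript_id = "u", dist_transcript = 9L, dist_cds = 9L)
  # window "TACG": offset -2 = TA (nullomer), -1 = AC, 0 = CG
  w <- junction_windows(jx, seqs = c(u = "TACG"), upstream = 2, downstream = 2)
  p <- profile_surprisal(w, st)
  expect_equal(p$stats$n, c(0L, 1L, 1L))
  expect_equal(p$stats$n_excluded, c(1L, 0L, 0L))
  expect_true(is.na(p$stats$mean_surprisal[1]))
})

test_that("a rare junction-joined k-mer produces the profile extreme at offset -1", {
  # windows share common flanking 2-mers but each junction joins the last
  # exon base to the next base as a rare dinucleotide: the exon-exon chain
  # peaks at offset -1, mirroring junction-driven surprisal spikes
  seqs <- c(u = "AAAACGAAAA", v = "AAAACGAAAA")
  tab <- count_kmers(c("AAAAAAAAAACG", strrep("A", 30), "ACAACAAC"), 2)
  st <- surprisal_table(tab)
  jx <- data.frame(kind = "exon_exon", chrom = "c", strand = "+", anchor = NA,
                   spliced_pos = 5L, cds_pos = 5L, phase = 2L,
                   transcript_id = c("u", "v"),
                   dist_transcript = 9L, dist_cds = 9L)
  w <- junction_windows(jx, seqs = seqs, upstream = 4, downstream = 4)
  p <- profile_surprisal(w, st)
  m <- p$stats$mean_surprisal
  expect_equal(p$stats$offset[which.max(m)], -1L)
})

test_that("amino-acid expansion tiles each residue value over 3 nt offsets in phase", {
  vals <- matrix(c(1, 2), nrow = 1)
  aap <- structure(list(stats = NULL, values = vals, offsets = c(0L, 1L),
                        k = 1L), class = "junction_profile")
  aap$stats <- kmersurprisal:::.summarize_profile(vals, c(0L, 1L))
  e0 <- aa_profile_expand(aap, phases = 0L, k_nt = 3L)
  got0 <- e0$values[1, match(0:5, e0$offsets)]
  expect_equal(got0, c(1, 1, 1, 2, 2, 2))
  e1 <- aa_profile_expand(aap, phases = 1L, k_nt = 3L)
  got1 <- e1$values[1, match(-1:4, e1$offsets)]
  expect_equal(got1, c(1, 1, 1, 2, 2, 2))
  e2 <- aa_profile_expand(aap, phases = 2L, k_nt = 3L)
  got2 <- e2$values[1, match(-2:3, e2$offsets)]
  expect_equal(got2, c(1, 1, 1, 2, 2, 2))
  expect_error(aa_profile_expand(aap, 0L, 8L), class = "ks_invalid_request")

  # conservation on fixture junctions: every non-NA value occupies runs of
  # exactly 3 consecutive nucleotide offsets per junction
  gen <- small_fixture()
  jx <- derive_junctions(gen$models, filter_kind = "cds_ends", min_dist = 30)
  jx <- jx[jx$kind == "exon_exon", ]
  jx$aa_pos <- jx$cds_pos %/% 3L
  peps <- vapply(gen$models, function(tx)
    translate_cds(cds_sequence(tx, gen$genome)), character(1))
  st <- surprisal_table(coding_kmer_table(gen$models, gen$genome, 3L, "aa"))
  w <- junction_windows(jx, seqs = peps, upstream = 8, downstream = 8,
                        anchor_col = "aa_pos")
  aaprof <- profile_surprisal(w, st)
  ex <- aa_profile_expand(aaprof, jx$phase, 9L)
  for (i in seq_len(nrow(ex$values))) {
    r <- rle(ex$values[i, ])
    expect_true(all(r$lengths[!is.na(r$values)] %% 3 == 0))
  }
})

test_that("coefficient of variation follows sd/mean with the inverse as alternate", {
  vals <- matrix(c(2, 4, 3, 3), nrow = 2)
  prof <- structure(list(stats = kmersurprisal:::.summarize_profile(vals, 0:1),
                         values = vals, offsets = 0:1, k = 1L),
                    class = "junction_profile")
  cv <- coefficient_of_variation(prof)
  expect_equal(cv$cv[1], sqrt(2) / 3)
  expect_equal(cv$mean_over_sd[1], 3 / sqrt(2))
  expect_equal(cv$cv[2], 0)            # sd 0, mean > 0
  expect_true(is.na(cv$mean_over_sd[2]))

  # larger k lowers the relative spread of junction surprisal on the fixture
  gen <- small_fixture()
  jx <- derive_junctions(gen$models, min_dist = 100)
  dj <- jx[jx$kind == "donor", ]
  w <- junction_windows(dj, genome = gen$genome, upstream = 30,
                        downstream = 30)
  mean_cv <- vapply(c(3L, 6L, 9L, 12L), function(k) {
    st <- surprisal_table(count_kmers(gen$genome, k, both_strands = TRUE))
    cv <- coefficient_of_variation(profile_surprisal(w, st))
    mean(cv$cv, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_cv) < 0))
})

test_that("positional dinucleotide frequencies count per offset", {
  jx <- data.frame(kind = "exon_exon", chrom = "c", strand = "+", anchor = NA,
                   spliced_pos = 2L, cds_pos = 2L, phase = 0L,
                   transcript_id = c("u", "v"),
                   dist_transcript = 9L, dist_cds = 9L)
  w <- junction_windows(jx, seqs = c(u = "CGAT", v = "CGTT"), upstream = 2,
                        downstream = 2)
  f <- positional_dinucleotide_frequency(w, "CG")
  expect_equal(f$offset, c(-2L, -1L, 0L))
  expect_equal(f$frequency, c(1, 0, 0))
  # near-uniform background sits near 1/16 per offset
  set.seed(9)
  ws <- vapply(1:400, function(i) random_dna(24, n_prob = 0), character(1))
  attr(ws, "upstream") <- 12L; attr(ws, "downstream") <- 12L
  fu <- positional_dinucleotide_frequency(ws, "GC")
  se3 <- 3 * sqrt((1 / 16) * (15 / 16) / 400)
  expect_true(all(abs(fu$frequency - 1 / 16) <= se3 + 0.01))
})
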