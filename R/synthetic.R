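# Seeded synthetic genome + annotation generator.
#
# Emulates the features the analysis modules look for in real Ensembl data:
# multi-transcript protein-coding genes whose introns start GT and end AG,
# a polypyrimidine tract and a branch-point consensus upstream of each
# acceptor, CDS lengths divisible by 3 with no internal stop, exon-skipping
# isoforms that share exons (exercising the multiple-transcript correction),
# and a first-order background chain with tunable CG-dinucleotide
# suppression.  A single RNG stream, seeded once per generation run and
# consumed in a fixed order, makes fixtures byte-reproducible.

#' Parameters for a synthetic genome fixture
#'
#' @param seed Integer seed; fully determines the fixture.
#' @param chrom_lengths Lengths (nt) of the background chromosomes.
#' @param base_frequencies Stationary base composition of the background
#'   chain (normalised internally); the default is tetrapod-like at 41% GC.
#' @param cg_suppression Multiplier in (0, 1] applied to the C->G transition
#'   of the background chain (then renormalised); 1 disables suppression.
#'   The default 0.2 mirrors the strong CpG depletion of tetrapod genomes.
#' @param n_genes Number of genes to plant.
#' @param exons_per_gene,exon_length,intron_length Integer ranges
#'   (min, max); introns must be at least 60 nt to hold their features.
#' @param transcripts_per_gene Range; genes with 2 transcripts get an
#'   exon-skipping isoform sharing all remaining exons.
#' @param polypyrimidine_length Tract length range (nt).
#' @param pyrimidine_prob Per-base probability that a tract base is C/T.
#' @param acceptor_gap Range of the gap (nt) between the tract 3' end and
#'   the AG acceptor motif.
#' @param branch_consensus Branch-point motif planted upstream of each
#'   acceptor.
#' @param branch_offset Range of the distance (nt) from the motif 3' end to
#'   the intron 3' end.
#' @param donor_motif,acceptor_motif Terminal intron dinucleotides.
#' @param intergenic_gap Range of the gap between consecutive genes.
#' @return A validated `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(seed = 1L,
                                  chrom_lengths = c(1000000L, 1000000L),
                                  base_frequencies = c(A = 0.295, C = 0.205,
                                                       G = 0.205, T = 0.295),
                                  cg_suppression = 0.2,
                                  n_genes = 40L,
                                  exons_per_gene = c(3L, 8L),
                                  exon_length = c(90L, 300L),
                                  intron_length = c(200L, 1500L),
                                  transcripts_per_gene = c(1L, 2L),
                                  polypyrimidine_length = c(10L, 20L),
                                  pyrimidine_prob = 0.85,
                                  acceptor_gap = c(4L, 8L),
                                  branch_consensus = "CTAAC",
                                  branch_offset = c(15L, 55L),
                                  donor_motif = "GT",
                                  acceptor_motif = "AG",
                                  intergenic_gap = c(1000L, 5000L)) {
  stopifnot(length(base_frequencies) == 4L, all(base_frequencies > 0),
            cg_suppression > 0, cg_suppression <= 1,
            intron_length[1] >= 60L, exon_length[1] >= 9L,
            all(chrom_lengths >= 1000L), n_genes >= 1L,
            pyrimidine_prob >= 0, pyrimidine_prob <= 1)
  rng <- function(r) stopifnot(length(r) == 2L, r[1] <= r[2])
  rng(exons_per_gene); rng(exon_length); rng(intron_length)
  rng(transcripts_per_gene); rng(polypyrimidine_length)
  if (transcripts_per_gene[2] > 2L)
    .ks_stop("at most 2 transcripts per gene are supported (one exon-skipping isoform)",
             "ks_invalid_request")
  rng(acceptor_gap); rng(branch_offset); rng(intergenic_gap)
  structure(list(
    seed = as.integer(seed),
    chrom_lengths = as.integer(chrom_lengths),
    base_frequencies = stats::setNames(base_frequencies / sum(base_frequencies),
                                       c("A", "C", "G", "T")),
    cg_suppression = cg_suppression,
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    polypyrimidine_length = as.integer(polypyrimidine_length),
    pyrimidine_prob = pyrimidine_prob,
    acceptor_gap = as.integer(acceptor_gap),
    branch_consensus = toupper(branch_consensus),
    branch_offset = as.integer(branch_offset),
    donor_motif = toupper(donor_motif),
    acceptor_motif = toupper(acceptor_motif),
    intergenic_gap = as.integer(intergenic_gap)
  ), class = "synthetic_genome_spec")
}

#' @export
print.synthetic_genome_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome_spec> seed=%d, %d chrom(s) totalling %s nt, %d genes, cg_suppression=%.2g\n",
    x$seed, length(x$chrom_lengths),
    format(sum(x$chrom_lengths), big.mark = ","), x$n_genes,
    x$cg_suppression))
  invisible(x)
}

.sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Sample background sequence from the CG-suppressed chain
#'
#' First-order Markov chain whose rows equal `base_frequencies` except that
#' the C->G transition is scaled by `cg_suppression` and the C row
#' renormalised. Uses (and advances) the current RNG stream; seed it for
#' reproducibility.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param length Sequence length (>= 1).
#' @return A nucleotide string.
#' @export
sample_background <- function(spec, length) {
  stopifnot(length >= 1)
  n <- as.integer(length)
  bf <- spec$base_frequencies
  P <- matrix(rep(bf, each = 4L), 4L, 4L,
              dimnames = list(names(bf), names(bf)))
  P["C", "G"] <- P["C", "G"] * spec$cg_suppression
  P["C", ] <- P["C", ] / sum(P["C", ])
  # cumulative thresholds per from-state for a branch-free sampling loop
  t1 <- P[, 1]; t2 <- t1 + P[, 2]; t3 <- t2 + P[, 3]
  u <- stats::runif(n)
  x <- integer(n)
  b0 <- cumsum(bf)
  x[1] <- 1L + (u[1] > b0[1]) + (u[1] > b0[2]) + (u[1] > b0[3])
  if (n > 1L) {
    for (i in 2:n) {
      p <- x[i - 1L]
      ui <- u[i]
      x[i] <- 1L + (ui > t1[p]) + (ui > t2[p]) + (ui > t3[p])
    }
  }
  paste(c("A", "C", "G", "T")[x], collapse = "")
}

# Build one gene in transcript orientation from raw background material.
# Returns NULL if the exon-skipping isoform ends up with an internal stop
# (the caller retries with fresh randomness).
.build_gene <- function(spec, raw, ex_lens, in_lens, skip) {
  region <- raw
  n_ex <- length(ex_lens)
  seg_len <- integer(2L * n_ex - 1L)
  seg_len[seq(1L, by = 2L, length.out = n_ex)] <- ex_lens
  if (n_ex > 1L) seg_len[seq(2L, by = 2L, length.out = n_ex - 1L)] <- in_lens
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L
  ex_start <- seg_start[seq(1L, by = 2L, length.out = n_ex)]
  ex_end <- seg_end[seq(1L, by = 2L, length.out = n_ex)]

  # intron features, written in transcript orientation
  if (n_ex > 1L) {
    for (i in seq_len(n_ex - 1L)) {
      is <- seg_start[2L * i]; ie <- seg_end[2L * i]
      ilen <- ie - is + 1L
      bc <- spec$branch_consensus
      b <- min(.sample_range(spec$branch_offset), ilen - nchar(bc) - 4L)
      bs <- ie - b - nchar(bc) + 1L
      substr(region, bs, bs + nchar(bc) - 1L) <- bc
      g <- .sample_range(spec$acceptor_gap)
      tlen <- .sample_range(spec$polypyrimidine_length)
      ts <- max(is + 2L, ie - 2L - g - tlen + 1L)
      te <- ie - 2L - g
      npy <- te - ts + 1L
      pyr <- stats::runif(npy) < spec$pyrimidine_prob
      tract <- ifelse(pyr, sample(c("C", "T"), npy, replace = TRUE),
                      sample(c("A", "G"), npy, replace = TRUE))
      substr(region, ts, te) <- paste(tract, collapse = "")
      substr(region, is, is + 1L) <- spec$donor_motif
      substr(region, ie - 1L, ie) <- spec$acceptor_motif
    }
  }

  # frame the full-length isoform: ATG start, TAA stop, no internal stops
  spl <- paste(substring(region, ex_start, ex_end), collapse = "")
  len <- nchar(spl)
  substr(spl, 1L, 3L) <- "ATG"
  substr(spl, len - 2L, len) <- "TAA"
  codons <- substring(spl, seq(1L, len, 3L), seq(3L, len, 3L))
  internal <- which(codons %in% c("TAA", "TAG", "TGA"))
  internal <- internal[internal < length(codons)]
  # replacing the leading T yields CAA/CAG/CGA, none of which is a stop
  for (i in internal) substr(spl, 3L * i - 2L, 3L * i - 2L) <- "C"

  # the skipping isoform must stay stop-free across its novel junction
  if (!is.na(skip)) {
    cb <- cumsum(ex_lens)
    a <- if (skip > 1L) cb[skip - 1L] else 0L
    spl2 <- paste0(substr(spl, 1L, a), substr(spl, a + ex_lens[skip] + 1L, len))
    cd2 <- substring(spl2, seq(1L, nchar(spl2), 3L), seq(3L, nchar(spl2), 3L))
    if (any(cd2[-length(cd2)] %in% c("TAA", "TAG", "TGA"))) return(NULL)
  }

  # write the framed spliced sequence back into the exon segments
  cb <- cumsum(ex_lens)
  for (i in seq_len(n_ex)) {
    a <- if (i > 1L) cb[i - 1L] else 0L
    substr(region, ex_start[i], ex_end[i]) <- substr(spl, a + 1L, cb[i])
  }
  list(region = region, ex_start = ex_start, ex_end = ex_end)
}

#' Plant annotated genes into background chromosomes
#'
#' Places non-overlapping protein-coding genes along the supplied
#' chromosomes. Every intron begins with the donor motif and ends with the
#' acceptor motif, carries a branch-point consensus and a polypyrimidine
#' tract upstream of the acceptor; every CDS starts ATG, ends TAA, has
#' length divisible by 3 and no internal stop. Genes drawn with two
#' transcripts get an exon-skipping second isoform (the skipped internal
#' exon has length divisible by 3) sharing all other exons.
#'
#' Uses the current RNG stream; [generate_synthetic_genome()] wraps it with
#' the spec's seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param chroms Named character vector of background chromosomes.
#' @return List with `sequences` (edited chromosomes), `models`
#'   (`transcript_models`), `peptides` (named by transcript id) and `genes`
#'   (summary data frame).
#' @export
plant_genes <- function(spec, chroms) {
  models <- list()
  peptides <- character(0)
  genes <- list()
  gi <- 0L
  n_per <- diff(round(spec$n_genes * cumsum(c(0, nchar(chroms))) /
                        sum(nchar(chroms))))
  for (ci in seq_along(chroms)) {
    s <- chroms[[ci]]
    cursor <- .sample_range(spec$intergenic_gap)
    for (g in seq_len(n_per[ci])) {
      gi <- gi + 1L
      placed <- FALSE
      for (attempt in 1:30) {
        n_ex <- .sample_range(spec$exons_per_gene)
        # transcript count is structural, not sequence randomness: genes get
        # the upper bound of the range whenever an internal exon exists to
        # skip, so seeds change sequences but not fixture structure
        n_tx <- if (spec$transcripts_per_gene[2] > 1L && n_ex >= 3L)
          spec$transcripts_per_gene[2] else spec$transcripts_per_gene[1]
        ex_lens <- sample(spec$exon_length[1]:spec$exon_length[2], n_ex,
                          replace = TRUE)
        skip <- if (n_tx > 1L) .sample_range(c(2L, n_ex - 1L)) else NA_integer_
        if (!is.na(skip)) {
          ex_lens[skip] <- ex_lens[skip] - ex_lens[skip] %% 3L
        }
        ex_lens[n_ex] <- ex_lens[n_ex] + (3L - sum(ex_lens) %% 3L) %% 3L
        in_lens <- if (n_ex > 1L)
          sample(spec$intron_length[1]:spec$intron_length[2], n_ex - 1L,
                 replace = TRUE) else integer(0)
        L <- sum(ex_lens) + sum(in_lens)
        if (cursor + L + spec$intergenic_gap[1] > nchar(s))
          .ks_stop(sprintf("chromosome %d too short for requested genes",
                           ci), "ks_generation_error")
        strand <- sample(c("+", "-"), 1L)
        raw <- substr(s, cursor + 1L, cursor + L)
        if (strand == "-") raw <- .revcomp(raw)
        built <- .build_gene(spec, raw, ex_lens, in_lens, skip)
        if (is.null(built)) next
        placed <- TRUE
        break
      }
      if (!placed)
        .ks_stop("gene placement failed after bounded retries",
                 "ks_generation_error")
      region <- built$region
      substr(s, cursor + 1L, cursor + L) <-
        if (strand == "-") .revcomp(region) else region
      # transcript-oriented intervals -> genomic 0-based half-open
      a <- built$ex_start - 1L   # 0-based within region
      b <- built$ex_end
      if (strand == "+") {
        gs <- cursor + a; ge <- cursor + b
      } else {
        gs <- cursor + L - b; ge <- cursor + L - a
      }
      gene_id <- sprintf("SYNG%04d", gi)
      chrom_name <- names(chroms)[ci]
      tx_exsets <- list(seq_len(n_ex))
      if (!is.na(skip)) tx_exsets <- c(tx_exsets, list(setdiff(seq_len(n_ex), skip)))
      for (t in seq_along(tx_exsets)) {
        idx <- tx_exsets[[t]]
        exdf <- data.frame(start = gs[idx], end = ge[idx])
        tid <- sprintf("%s.t%d", gene_id, t)
        tx <- structure(list(
          transcript_id = tid, gene_id = gene_id, chrom = chrom_name,
          strand = strand, exons = exdf, cds = exdf,
          is_protein_coding = TRUE, is_gencode_basic = TRUE
        ), class = "transcript_model")
        models[[tid]] <- tx
        cb <- cumsum(built$ex_end - built$ex_start + 1L)
        spl <- paste(substring(region, built$ex_start[idx],
                               built$ex_end[idx]), collapse = "")
        peptides[[tid]] <- translate_cds(spl)
      }
      genes[[gi]] <- data.frame(
        gene_id = gene_id, chrom = chrom_name, strand = strand,
        start = cursor, end = cursor + L, n_exons = n_ex,
        n_transcripts = length(tx_exsets),
        skipped_exon = if (is.na(skip)) NA_integer_ else skip)
      cursor <- cursor + L + .sample_range(spec$intergenic_gap)
    }
    chroms[[ci]] <- s
  }
  list(sequences = chroms,
       models = structure(models[order(names(models))],
                          class = "transcript_models"),
       peptides = peptides,
       genes = do.call(rbind, genes))
}

#' Generate a complete synthetic genome fixture in memory
#'
#' Seeds a private RNG stream from `spec$seed`, samples the background
#' chromosomes and plants the genes; identical specs yield identical output.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List with `genome` (named chromosome strings), `models`
#'   (`transcript_models`), `peptides`, `genes` and `spec`.
#' @export
generate_synthetic_genome <- function(spec) {
  .with_seed(spec$seed, {
    chroms <- stats::setNames(
      vapply(spec$chrom_lengths, function(n) sample_background(spec, n),
             character(1)),
      paste0("chr", seq_along(spec$chrom_lengths)))
    pg <- plant_genes(spec, chroms)
    structure(list(genome = pg$sequences, models = pg$models,
                   peptides = pg$peptides, genes = pg$genes, spec = spec),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chrom(s), %s nt, %d transcripts (%d genes)\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              length(x$models), nrow(x$genes)))
  invisible(x)
}

.write_gtf <- function(models, path) {
  lines <- character(0)
  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  gattr <- function(gid) sprintf('gene_id "%s";', gid)
  tattr <- function(gid, tid, extra = "")
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "protein_coding"; tag "basic";%s',
            gid, tid, extra)
  row <- function(chrom, feat, s0, e0, strand, frame, attr)
    paste(chrom, "kmersurprisal", feat, s0 + 1L, e0, ".", strand, frame, attr,
          sep = "\t")
  for (gid in sort(names(by_gene))) {
    txs <- by_gene[[gid]]
    allx <- do.call(rbind, lapply(txs, `[[`, "exons"))
    g1 <- txs[[1]]
    lines <- c(lines, row(g1$chrom, "gene", min(allx$start), max(allx$end),
                          g1$strand, ".", gattr(gid)))
    for (tx in txs) {
      lines <- c(lines, row(tx$chrom, "transcript", min(tx$exons$start),
                            max(tx$exons$end), tx$strand, ".",
                            tattr(gid, tx$transcript_id)))
      cum <- 0L
      for (i in seq_len(nrow(tx$exons))) {
        lines <- c(lines,
                   row(tx$chrom, "exon", tx$exons$start[i], tx$exons$end[i],
                       tx$strand, ".",
                       tattr(gid, tx$transcript_id,
                             sprintf(' exon_number "%d";', i))))
        frame <- (3L - cum %% 3L) %% 3L
        lines <- c(lines,
                   row(tx$chrom, "CDS", tx$cds$start[i], tx$cds$end[i],
                       tx$strand, frame,
                       tattr(gid, tx$transcript_id,
                             sprintf(' exon_number "%d";', i))))
        cum <- cum + tx$cds$end[i] - tx$cds$start[i]
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic fixture to disk
#'
#' Writes `genome.fa` (60-column FASTA), `annotation.gtf` (Ensembl-dialect
#' gene/transcript/exon/CDS rows with `transcript_biotype "protein_coding"`
#' and `tag "basic"`), `peptides.fa` (expected translations, one record per
#' transcript) and `manifest.json` (spec parameters plus planted gene
#' coordinates). Outputs are byte-identical for identical specs.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`fasta`, `gtf`, `peptides`,
#'   `manifest`), with the in-memory generation attached as attribute
#'   `generation`.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_synthetic_genome(spec)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  pep <- file.path(dir, "peptides.fa")
  manifest <- file.path(dir, "manifest.json")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$genome), fasta,
                              width = 60L)
  .write_gtf(gen$models, gtf)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(gen$peptides), pep,
                              width = 60L)
  jsonlite::write_json(list(spec = unclass(gen$spec), genes = gen$genes),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(fasta = fasta, gtf = gtf, peptides = pep,
                 manifest = manifest),
            generation = gen)
}
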