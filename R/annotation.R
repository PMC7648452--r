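# Ensembl-dialect GTF parsing, transcript models, splice junctions, and the
# multiple-transcript genomic-locus correction.
#
# Coordinates are 0-based half-open everywhere inside the package; GTF input
# (1-based inclusive) is converted at the parser boundary.  Exons and CDS
# intervals are stored in transcript (5'->3') order, i.e. descending genomic
# coordinate on the minus strand.

.gtf_attr1 <- function(attr, key) {
  pat <- paste0(key, ' "([^"]*)"')
  m <- regexpr(pat, attr)
  out <- rep(NA_character_, length(attr))
  hit <- m > 0
  out[hit] <- sub(pat, "\\1", regmatches(attr, m))
  out
}

.gtf_tags <- function(attr) {
  regmatches(attr, gregexpr('tag "([^"]*)"', attr)) |>
    lapply(function(x) sub('tag "([^"]*)"', "\\1", x))
}

#' Parse Ensembl-dialect GTF annotation into transcript models
#'
#' Reads gene/transcript/exon/CDS features and assembles one strand-aware
#' model per transcript. By default only transcripts that are protein coding
#' (attribute `transcript_biotype` or `transcript_type`) and carry a GENCODE
#' `tag "basic"` (5'- and 3'-complete transcripts) are retained.
#'
#' @param path Path to a GTF file.
#' @param protein_coding_only Keep only protein-coding transcripts.
#' @param basic_only Keep only transcripts tagged GENCODE basic.
#' @return A `transcript_models` object: a named list of `transcript_model`s,
#'   each with `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` and
#'   `cds` (data frames with 0-based half-open `start`/`end`, transcript
#'   order), `is_protein_coding`, `is_gencode_basic`.
#' @export
parse_gtf <- function(path, protein_coding_only = TRUE, basic_only = TRUE) {
  if (!file.exists(path))
    .ks_stop(paste0("GTF file not found: ", path), "ks_io_error")
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(structure(list(), class = "transcript_models"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    .ks_stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields",
                     lineno[bad[1]]), "ks_parse_error")
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feat <- m[, 3]
  sel <- feat %in% c("exon", "CDS")
  start <- suppressWarnings(as.integer(m[sel, 4]))
  end <- suppressWarnings(as.integer(m[sel, 5]))
  if (anyNA(start) || anyNA(end) || any(start < 1) || any(end < start))
    .ks_stop(sprintf("malformed GTF line %d: bad coordinates",
                     lineno[sel][which(is.na(start) | is.na(end) |
                                         start < 1 | end < start)[1]]),
             "ks_parse_error")
  attr_str <- m[sel, 9]
  df <- data.frame(
    chrom = m[sel, 1], feature = feat[sel],
    start = start - 1L, end = end, strand = m[sel, 7],
    gene_id = .gtf_attr1(attr_str, "gene_id"),
    transcript_id = .gtf_attr1(attr_str, "transcript_id"),
    stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    .ks_stop("GTF records must be stranded (+/-)", "ks_parse_error")
  biotype <- .gtf_attr1(attr_str, "transcript_biotype")
  alt <- .gtf_attr1(attr_str, "transcript_type")
  biotype[is.na(biotype)] <- alt[is.na(biotype)]
  df$biotype <- biotype
  df$basic <- vapply(.gtf_tags(attr_str), function(t) "basic" %in% t, logical(1))
  if (anyNA(df$transcript_id))
    .ks_stop("exon/CDS record lacking transcript_id", "ks_parse_error")

  models <- lapply(split(df, df$transcript_id), .build_transcript_model)
  pc <- vapply(models, `[[`, logical(1), "is_protein_coding")
  bs <- vapply(models, `[[`, logical(1), "is_gencode_basic")
  if (protein_coding_only) models <- models[pc[names(models)]]
  if (basic_only) models <- models[bs[names(models)]]
  models <- models[order(names(models))]
  structure(models, class = "transcript_models")
}

.build_transcript_model <- function(rows) {
  ex <- rows[rows$feature == "exon", , drop = FALSE]
  cd <- rows[rows$feature == "CDS", , drop = FALSE]
  tid <- rows$transcript_id[1]
  if (!nrow(ex) && nrow(cd))
    .ks_stop(sprintf("transcript %s has CDS but no exons", tid),
             "ks_model_error")
  strand <- unique(rows$strand)
  chrom <- unique(rows$chrom)
  if (length(strand) != 1L || length(chrom) != 1L)
    .ks_stop(sprintf("transcript %s spans multiple contigs/strands", tid),
             "ks_model_error")
  tx_order <- function(d) {
    d <- d[order(d$start), c("start", "end"), drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)]))
      .ks_stop(sprintf("transcript %s has overlapping intervals", tid),
               "ks_model_error")
    if (strand == "-") d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  exons <- tx_order(ex)
  cds <- if (nrow(cd)) tx_order(cd) else exons[0, , drop = FALSE]
  # every CDS interval must lie within some exon
  if (nrow(cds)) {
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside))
      .ks_stop(sprintf("transcript %s has CDS outside its exons", tid),
               "ks_model_error")
  }
  structure(list(
    transcript_id = tid, gene_id = rows$gene_id[1],
    chrom = chrom, strand = strand, exons = exons, cds = cds,
    is_protein_coding = isTRUE(any(rows$biotype == "protein_coding")),
    is_gencode_basic = any(rows$basic)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exons, %d CDS segments\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts\n", length(x)))
  invisible(x)
}

# Genomic 0-based coordinate of every spliced base, in transcript order.
.posmap <- function(iv, strand) {
  if (!nrow(iv)) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(i) {
    if (strand == "+") seq.int(iv$start[i], iv$end[i] - 1L)
    else seq.int(iv$end[i] - 1L, iv$start[i])
  }), use.names = FALSE)
}

.check_intervals <- function(tx, iv, genome) {
  if (!tx$chrom %in% names(genome))
    .ks_stop(sprintf("contig %s not in genome", tx$chrom), "ks_coordinate_error")
  n <- nchar(genome[[tx$chrom]])
  if (nrow(iv) && (min(iv$start) < 0L || max(iv$end) > n))
    .ks_stop(sprintf("transcript %s extends past contig %s bounds",
                     tx$transcript_id, tx$chrom), "ks_coordinate_error")
}

.splice <- function(tx, iv, genome) {
  .check_intervals(tx, iv, genome)
  g <- genome[[tx$chrom]]
  asc <- iv[order(iv$start), , drop = FALSE]
  s <- paste(substring(g, asc$start + 1L, asc$end), collapse = "")
  if (tx$strand == "-") s <- .revcomp(toupper(s)) else s <- toupper(s)
  s
}

#' Spliced and coding sequences of a transcript
#'
#' `spliced_sequence()` concatenates the exon sequences in transcript order
#' (reverse-complemented for minus-strand transcripts); `cds_sequence()` does
#' the same restricted to the annotated CDS intervals, so it includes the
#' stop codon if annotated within the CDS.
#'
#' @param tx A `transcript_model`.
#' @param genome Named character vector of contig sequences (see
#'   [read_genome_fasta()]).
#' @return A single character string.
#' @export
spliced_sequence <- function(tx, genome) .splice(tx, tx$exons, genome)

#' @rdname spliced_sequence
#' @export
cds_sequence <- function(tx, genome) {
  if (!nrow(tx$cds))
    .ks_stop(sprintf("transcript %s has no CDS", tx$transcript_id),
             "ks_model_error")
  .splice(tx, tx$cds, genome)
}

#' Translate a coding sequence
#'
#' Standard codon table (61 sense codons, 3 stops). A single terminal stop
#' codon is dropped; an internal stop or a length not divisible by 3 is an
#' error.
#'
#' @param cds A nucleotide string whose length is a multiple of 3.
#' @return Peptide string over the 20 standard amino-acid letters.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    .ks_stop("CDS length must be a positive multiple of 3", "ks_frame_error")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa))
    .ks_stop(sprintf("untranslatable codon: %s", codons[is.na(aa)][1]),
             "ks_frame_error")
  stops <- which(aa == "*")
  if (any(stops < length(aa)))
    .ks_stop(sprintf("premature stop codon at codon %d", stops[1]),
             "ks_premature_stop")
  if (length(stops)) aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# Spliced-transcript offset of the CDS start and the CDS length, or NULL.
.cds_span_spliced <- function(tx) {
  if (!nrow(tx$cds)) return(NULL)
  pm <- .posmap(tx$exons, tx$strand)
  cpm <- .posmap(tx$cds, tx$strand)
  start <- match(cpm[1], pm) - 1L
  list(start = start, len = length(cpm))
}

#' Derive splice junctions from transcript models
#'
#' For every intron of a multi-exon transcript, emits one donor site (5'
#' splice site; profile offset 0 is the first intron base, GT in canonical
#' introns), one acceptor site (3' splice site; offset 0 is the first base of
#' the downstream exon) and one exon-exon site (the joint in the spliced
#' transcript; offset 0 is the first base of the downstream exon in spliced
#' coordinates). In every case offsets -1 and 0 straddle the junction.
#'
#' Junctions closer than `min_dist` to the relevant sequence ends are removed:
#' distance to the transcript ends (in spliced transcript coordinates) under
#' `filter_kind = "transcript_ends"`, or to the translation start/end (in
#' spliced CDS coordinates) under `"cds_ends"`.
#'
#' @param x A `transcript_model` or `transcript_models` collection.
#' @param filter_kind Which ends the `min_dist` filter measures to.
#' @param min_dist Minimum distance in nt (default 100); junctions at
#'   distances `< min_dist` are dropped.
#' @return Data frame with columns `kind`, `chrom`, `strand`, `anchor`
#'   (genomic 0-based position of offset 0 for donor/acceptor; NA for
#'   exon-exon), `spliced_pos`, `cds_pos`, `phase`, `transcript_id`,
#'   `dist_transcript`, `dist_cds`.
#' @export
derive_junctions <- function(x, filter_kind = c("transcript_ends", "cds_ends"),
                             min_dist = 100L) {
  filter_kind <- match.arg(filter_kind)
  if (inherits(x, "transcript_models") || (is.list(x) && !inherits(x, "transcript_model"))) {
    out <- do.call(rbind, lapply(x, .junctions_one))
    if (is.null(out)) out <- .junctions_one(NULL)
  } else {
    out <- .junctions_one(x)
  }
  rownames(out) <- NULL
  d <- if (filter_kind == "transcript_ends") out$dist_transcript else out$dist_cds
  out[!is.na(d) & d >= min_dist, , drop = FALSE]
}

.junctions_one <- function(tx) {
  empty <- data.frame(kind = character(0), chrom = character(0),
                      strand = character(0), anchor = integer(0),
                      spliced_pos = integer(0), cds_pos = integer(0),
                      phase = integer(0), transcript_id = character(0),
                      dist_transcript = integer(0), dist_cds = integer(0))
  if (is.null(tx)) return(empty)
  ne <- nrow(tx$exons)
  if (ne < 2L) return(empty)
  L <- tx$exons$end - tx$exons$start
  cum <- cumsum(L)[-ne]            # junction positions in spliced coords
  total <- sum(L)
  up <- seq_len(ne - 1L)
  dn <- up + 1L
  if (tx$strand == "+") {
    donor_anchor <- tx$exons$end[up]        # first intron base
    acceptor_anchor <- tx$exons$start[dn]   # first base of downstream exon
  } else {
    donor_anchor <- tx$exons$start[up] - 1L
    acceptor_anchor <- tx$exons$end[dn] - 1L
  }
  dist_tx <- pmin(cum, total - cum)
  span <- .cds_span_spliced(tx)
  if (is.null(span)) {
    cds_pos <- rep(NA_integer_, length(cum))
    dist_cds <- cds_pos
  } else {
    cds_pos <- cum - span$start
    inside <- cds_pos > 0L & cds_pos < span$len
    dist_cds <- ifelse(inside, pmin(cds_pos, span$len - cds_pos), NA_integer_)
    cds_pos[!inside] <- NA_integer_
  }
  one <- function(kind, anchor) data.frame(
    kind = kind, chrom = tx$chrom, strand = tx$strand, anchor = anchor,
    spliced_pos = cum, cds_pos = cds_pos, phase = cds_pos %% 3L,
    transcript_id = tx$transcript_id,
    dist_transcript = dist_tx, dist_cds = dist_cds,
    stringsAsFactors = FALSE)
  rbind(one("donor", donor_anchor),
        one("acceptor", acceptor_anchor),
        one("exon_exon", rep(NA_integer_, length(cum))))
}

#' Map spliced-transcript offsets to genomic loci
#'
#' Returns the genomic locus key (chrom, strand, start, end; 0-based
#' half-open outer span) of the k-mer whose first base sits at each spliced
#' offset. For k-mers spanning an exon-exon junction the key spans the
#' intervening intron, so `end - start > k`.
#'
#' @param tx A `transcript_model`.
#' @param spliced_offset Integer vector of 0-based offsets into the spliced
#'   sequence.
#' @param k k-mer length in nt.
#' @param within `"transcript"` (spliced exons) or `"cds"` (spliced CDS).
#' @return Data frame `chrom`, `strand`, `start`, `end`.
#' @export
map_to_locus <- function(tx, spliced_offset, k, within = c("transcript", "cds")) {
  within <- match.arg(within)
  iv <- if (within == "transcript") tx$exons else tx$cds
  pm <- .posmap(iv, tx$strand)
  o <- as.integer(spliced_offset)
  if (any(o < 0L) || any(o + k > length(pm)))
    .ks_stop("spliced offset out of range", "ks_coordinate_error")
  first <- pm[o + 1L]
  last <- pm[o + k]
  data.frame(chrom = tx$chrom, strand = tx$strand,
             start = pmin(first, last),
             end = pmax(first, last) + 1L,
             stringsAsFactors = FALSE)
}

#' Deduplicate k-mer occurrences by genomic locus
#'
#' The multiple-transcript correction: exons shared between transcripts of a
#' gene would otherwise contribute the same k-mers repeatedly, so exactly one
#' occurrence is retained per distinct locus key (chrom, strand, start, end).
#' Retention is deterministic: occurrences are ordered by transcript id, then
#' locus. Two occurrences sharing a key but disagreeing on the k-mer string
#' (possible for junction-spanning k-mers with identical outer coordinates
#' but different splice chains) trigger a warning; the first is kept.
#'
#' @param occurrences Data frame with columns `kmer`, `chrom`, `strand`,
#'   `start`, `end`, `transcript_id`.
#' @return The deduplicated data frame.
#' @export
dedup_kmers <- function(occurrences) {
  if (!nrow(occurrences)) return(occurrences)
  o <- order(occurrences$transcript_id, occurrences$chrom,
             occurrences$strand, occurrences$start, occurrences$end)
  occ <- occurrences[o, , drop = FALSE]
  key <- paste(occ$chrom, occ$strand, occ$start, occ$end, sep = "\r")
  first <- !duplicated(key)
  kept_kmer <- occ$kmer[first][match(key, key[first])]
  clash <- occ$kmer != kept_kmer
  if (any(clash))
    warning(sprintf(
      "%d k-mer occurrence(s) share a genomic locus key but differ in sequence (splice-chain collision); first occurrence kept",
      sum(clash)), call. = FALSE)
  out <- occ[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locus-corrected k-mer tables for coding sequence spaces
#'
#' Builds the coding-mRNA or amino-acid k-mer count table over a set of
#' transcript models, applying the multiple-transcript correction: every
#' k-mer occurrence is keyed by its genomic locus (via [map_to_locus()]) and
#' counted once per distinct locus, so duplicating a transcript in the
#' annotation cannot change the table.
#'
#' @param models A `transcript_models` collection (protein coding).
#' @param genome Named character vector of contig sequences.
#' @param k k-mer length in the target space (nt for `"mrna"`, residues for
#'   `"aa"`; an amino-acid k-mer occupies `3k` nt).
#' @param space `"mrna"` (CDS-restricted nucleotide) or `"aa"` (peptide).
#' @return A `kmer_count_table`.
#' @export
coding_kmer_table <- function(models, genome, k, space = c("mrna", "aa")) {
  space <- match.arg(space)
  alphabet <- if (space == "mrna") nt_alphabet() else aa_alphabet()
  models <- models[order(vapply(models, `[[`, character(1), "transcript_id"))]
  occ <- lapply(models, function(tx) {
    if (!nrow(tx$cds)) return(NULL)
    cseq <- cds_sequence(tx, genome)
    if (space == "aa") {
      pep <- translate_cds(cseq)
      km <- extract_kmers(pep, k, alphabet)
      if (!nrow(km)) return(NULL)
      loci <- map_to_locus(tx, 3L * km$offset, 3L * k, within = "cds")
    } else {
      km <- extract_kmers(cseq, k, alphabet)
      if (!nrow(km)) return(NULL)
      loci <- map_to_locus(tx, km$offset, k, within = "cds")
    }
    cbind(data.frame(kmer = km$kmer, stringsAsFactors = FALSE), loci,
          data.frame(transcript_id = tx$transcript_id,
                     stringsAsFactors = FALSE))
  })
  occ <- do.call(rbind, occ)
  if (is.null(occ) || !nrow(occ))
    return(.new_count_table(k, alphabet,
                            stats::setNames(numeric(0), character(0)), 0))
  occ <- dedup_kmers(occ)
  tab <- table(occ$kmer)
  kmer_count_table(stats::setNames(as.numeric(tab), names(tab)), alphabet)
}

#' Write a junction table as TSV
#'
#' @param junctions Output of [derive_junctions()].
#' @param path Output path.
#' @param comments Optional header comment lines.
#' @export
write_junctions <- function(junctions, path, comments = character(0)) {
  .write_tsv(junctions, path, comments)
}
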