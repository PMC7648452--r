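# Dinucleotide-centric composition analyses: CG-segregated spectra, genome
# dinucleotide frequencies, phased codon usage, and per-position motif
# information content.

#' Count occurrences of a dinucleotide within k-mers
#'
#' Overlapping windows are scanned, so `"CGCG"` contains `"GC"` once and
#' `"CG"` twice.
#'
#' @param kmers Character vector (all length >= 2).
#' @param dinucleotide Two-letter query.
#' @return Integer vector of per-k-mer counts.
#' @export
count_dinucleotide_in_kmer <- function(kmers, dinucleotide) {
  stopifnot(nchar(dinucleotide) == 2L)
  if (!length(kmers)) return(integer(0))
  k <- unique(nchar(kmers))
  if (length(k) != 1L || k < 2L)
    .ks_stop("k-mers must share one length >= 2", "ks_invalid_request")
  out <- integer(length(kmers))
  for (j in seq_len(k - 1L)) {
    out <- out + (substr(kmers, j, j + 1L) == dinucleotide)
  }
  out
}

#' Segregate a k-mer spectrum by dinucleotide content
#'
#' Partitions the observed k-mers of a table into classes by the number of
#' occurrences of `dinucleotide` they contain, and summarises each class with
#' its occurrence spectrum and its surprisal distribution (over distinct
#' k-mers). With a suppressed dinucleotide such as CG, k-mers of higher class
#' are systematically rarer and therefore carry higher surprisal.
#'
#' @param table A nucleotide `kmer_count_table`.
#' @param dinucleotide Two-letter class-defining dinucleotide (default CG).
#' @return A `dinuc_class_spectrum`: `$spectra` (class, occurrences,
#'   n_kmers), `$surprisal` (per-class n_kmers, n_occurrences, min, q1,
#'   median, q3, max, mean of surprisal in bits), `$classes` (per-k-mer class
#'   vector named by k-mer).
#' @export
segregate_spectrum <- function(table, dinucleotide = "CG") {
  if (table$alphabet$name != "nucleotide")
    .ks_stop("spectrum segregation is defined for nucleotide tables",
             "ks_invalid_request")
  obs <- .observed(table)
  cls <- count_dinucleotide_in_kmer(obs$kmers, dinucleotide)
  surp <- -log2(obs$counts / table$total)
  spectra <- do.call(rbind, lapply(sort(unique(cls)), function(cc) {
    r <- rle(sort(obs$counts[cls == cc]))
    data.frame(class = cc, occurrences = r$values, n_kmers = r$lengths)
  }))
  qs <- do.call(rbind, lapply(sort(unique(cls)), function(cc) {
    s <- surp[cls == cc]
    q <- stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(class = cc, n_kmers = length(s),
               n_occurrences = sum(obs$counts[cls == cc]),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               mean = mean(s))
  }))
  structure(list(dinucleotide = dinucleotide, spectra = spectra,
                 surprisal = qs,
                 classes = stats::setNames(cls, obs$kmers)),
            class = "dinuc_class_spectrum")
}

#' @export
print.dinuc_class_spectrum <- function(x, ...) {
  cat(sprintf("<dinuc_class_spectrum> %s classes 0..%d over %d k-mers\n",
              x$dinucleotide, max(x$surprisal$class), length(x$classes)))
  print(x$surprisal)
  invisible(x)
}

#' Genome dinucleotide frequencies
#'
#' Counts every overlapping dinucleotide window across the sequences
#' (forward strand; plus the reverse-complement strand when
#' `include_revcomp = TRUE`), normalised to sum to 1 over the 16
#' dinucleotides. Windows containing foreign symbols are skipped.
#'
#' @param sequences Character vector or XStringSet of nucleotide sequences.
#' @param include_revcomp Also count the reverse complement of each sequence.
#' @return Named numeric vector of the 16 dinucleotide frequencies
#'   (lexicographic order).
#' @export
dinucleotide_frequency <- function(sequences, include_revcomp = FALSE) {
  tab <- count_kmers(sequences, 2L, nt_alphabet(),
                     both_strands = include_revcomp)
  all16 <- .decode_codes(0:15, 2L, nt_alphabet())
  out <- stats::setNames(numeric(16), all16)
  if (tab$total > 0) {
    out[names(tab$counts)] <- tab$counts / tab$total
  }
  out
}

#' Phased dinucleotide usage within coding sequences
#'
#' Assigns every overlapping dinucleotide within each CDS to a codon phase by
#' its start offset mod 3: phase 0 spans codon positions 1-2, phase 1 spans
#' positions 2-3, and phase 2 joins position 3 to position 1 of the next
#' codon. Windows never cross CDS record boundaries. Fractions are reported
#' per dinucleotide; an unskewed dinucleotide sits near (1/3, 1/3, 1/3).
#'
#' @param cds_sequences Character vector of CDS sequences, each with length a
#'   multiple of 3.
#' @return Data frame with columns `dinucleotide`, `phase0`, `phase1`,
#'   `phase2` (fractions summing to 1 per observed dinucleotide) and an
#'   attribute `counts` (16 x 3 count matrix).
#' @export
phased_dinucleotide_usage <- function(cds_sequences) {
  seqs <- .as_char_seqs(cds_sequences)
  if (any(nchar(seqs) %% 3L != 0L))
    .ks_stop("every CDS length must be a multiple of 3", "ks_frame_error")
  all16 <- .decode_codes(0:15, 2L, nt_alphabet())
  counts <- matrix(0, 16, 3, dimnames = list(all16, paste0("phase", 0:2)))
  for (s in seqs) {
    n <- nchar(s)
    if (n < 2L) next
    off <- 0:(n - 2L)
    dn <- substring(s, off + 1L, off + 2L)
    ok <- grepl("^[ACGT]{2}$", dn)
    if (!any(ok)) next
    t2 <- table(factor(dn[ok], levels = all16),
                factor(off[ok] %% 3L, levels = 0:2))
    counts <- counts + as.matrix(t2)
  }
  tot <- rowSums(counts)
  frac <- counts / ifelse(tot > 0, tot, NA_real_)
  out <- data.frame(dinucleotide = all16, phase0 = frac[, 1],
                    phase1 = frac[, 2], phase2 = frac[, 3],
                    row.names = NULL)
  attr(out, "counts") <- counts
  out
}

#' Per-position information content of aligned sequences
#'
#' For each column of an alignment of equal-length nucleotide strings,
#' computes `2 - H` bits, where H is the Shannon entropy of the column's base
#' frequencies: the representation used in sequence-logo motif figures, where
#' a fully conserved column scores 2 bits and a uniform column 0. Foreign
#' symbols are ignored (frequencies are over valid bases only); no
#' small-sample correction is applied.
#'
#' @param strings Character vector of equal-length nucleotide strings.
#' @return Numeric vector of per-position information in \[0, 2\] bits.
#' @export
position_information <- function(strings) {
  if (!length(strings))
    .ks_stop("empty alignment: information is undefined",
             "ks_undefined_distribution")
  strings <- toupper(strings)
  L <- unique(nchar(strings))
  if (length(L) != 1L)
    .ks_stop("aligned strings must share one length", "ks_invalid_request")
  m <- matrix(unlist(strsplit(strings, NULL)), ncol = L, byrow = TRUE)
  vapply(seq_len(L), function(j) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return(NA_real_)
    p <- table(col) / length(col)
    2 + sum(p * log2(p))
  }, numeric(1))
}
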