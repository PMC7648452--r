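# k-mer extraction, counting, and information statistics.
#
# k-mers over the nucleotide alphabet are encoded as base-4 integers (2 bits
# per base) held in doubles, which are exact up to 2^53 and therefore cover
# nucleotide k <= 16 and amino-acid k <= 11.  Small alphabets and k admit a
# dense count array indexed by code; everything else is stored sparsely as a
# named vector sorted in lexicographic k-mer order.

# ---- encoding ---------------------------------------------------------------

# Symbol digits (1..A) of one sequence; NA for foreign symbols.
.seq_digits <- function(seq, alphabet) {
  match(strsplit(seq, NULL)[[1]], alphabet$symbols)
}

# Codes of every valid window of one digit vector.  A window is valid only if
# all k symbols belong to the alphabet ("consisting fully of" the alphabet);
# invalid windows are skipped, never truncated.
.window_codes <- function(digits, k, A) {
  n <- length(digits)
  nw <- n - k + 1L
  if (nw < 1L) return(list(offsets = integer(0), codes = numeric(0)))
  valid <- !is.na(digits)
  d0 <- digits - 1L
  d0[!valid] <- 0L
  code <- numeric(nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(k)) {
    idx <- j:(nw + j - 1L)
    code <- code * A + d0[idx]
    ok <- ok & valid[idx]
  }
  list(offsets = which(ok) - 1L, codes = code[ok])
}

# Encode same-length k-mer strings to codes (NA if any foreign symbol).
.encode_kmers <- function(kmers, k, alphabet) {
  if (!length(kmers)) return(numeric(0))
  if (any(nchar(kmers) != k))
    .ks_stop("all k-mers must have length k", "ks_invalid_request")
  m <- matrix(match(unlist(strsplit(kmers, NULL)), alphabet$symbols), nrow = k)
  pw <- alphabet$size^((k - 1L):0L)
  colSums((m - 1) * pw)
}

# Decode numeric codes back to k-mer strings.
.decode_codes <- function(codes, k, alphabet) {
  if (!length(codes)) return(character(0))
  A <- alphabet$size
  cols <- vector("list", k)
  c2 <- codes
  for (j in k:1) {
    dig <- c2 %% A
    c2 <- (c2 - dig) / A
    cols[[j]] <- alphabet$symbols[dig + 1]
  }
  do.call(paste0, cols)
}

# ---- extraction and counting ------------------------------------------------

#' Extract k-mers from a sequence
#'
#' Slides a window of width `k` across `sequence` and returns every window
#' made up entirely of alphabet symbols, with its 0-based start offset.
#' Windows containing any foreign symbol (e.g. `N`) are skipped whole.
#' Lowercase (soft-masked) symbols are uppercased first.
#'
#' @param sequence A single character string.
#' @param k Window width, an integer >= 1.
#' @param alphabet A [nt_alphabet()] or [aa_alphabet()].
#' @return A data frame with columns `offset` (0-based) and `kmer`; zero rows
#'   for sequences shorter than `k`.
#' @examples
#' extract_kmers("ACGNT", 2)   # windows GN and NT are skipped
#' @export
extract_kmers <- function(sequence, k, alphabet = nt_alphabet()) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  sequence <- toupper(sequence)
  d <- .seq_digits(sequence, alphabet)
  w <- .window_codes(d, as.integer(k), alphabet$size)
  data.frame(offset = w$offsets,
             kmer = if (length(w$offsets))
               substring(sequence, w$offsets + 1L, w$offsets + k)
             else character(0),
             stringsAsFactors = FALSE)
}

.new_count_table <- function(k, alphabet, counts, total, dense = FALSE) {
  structure(list(k = as.integer(k), alphabet = alphabet, counts = counts,
                 total = total, dense = dense),
            class = "kmer_count_table")
}

#' Count k-mers across sequences
#'
#' Aggregates k-mer occurrence counts over a collection of sequences. Windows
#' never span record boundaries and windows containing foreign symbols are
#' skipped. With `both_strands = TRUE` (nucleotide alphabet only) the reverse
#' complement of every sequence is counted as an additional independent
#' sequence, so palindromic k-mers are counted on both strands.
#'
#' @param sequences Character vector or `XStringSet`.
#' @param k Window width.
#' @param alphabet Alphabet over which windows must be complete.
#' @param both_strands Also count the reverse complement of each sequence.
#' @return A `kmer_count_table` with fields `k`, `alphabet`, `counts` (named
#'   numeric vector in lexicographic k-mer order; absent k-mers are nullomers
#'   with implicit count 0) and `total` (number of accepted windows).
#' @examples
#' count_kmers("ACGTACGT", 3)
#' count_kmers("ACGT", 2, both_strands = TRUE)
#' @export
count_kmers <- function(sequences, k, alphabet = nt_alphabet(),
                        both_strands = FALSE) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  if (both_strands && alphabet$name != "nucleotide")
    .ks_stop("both_strands counting is only defined for the nucleotide alphabet",
             "ks_invalid_request")
  seqs <- .as_char_seqs(sequences)
  seqs <- seqs[nchar(seqs) > 0L]
  if (both_strands && length(seqs)) seqs <- c(seqs, .revcomp(seqs))
  codes <- lapply(seqs, function(s) {
    .window_codes(.seq_digits(s, alphabet), k, alphabet$size)$codes
  })
  codes <- unlist(codes, use.names = FALSE)
  total <- length(codes)
  if (!total)
    return(.new_count_table(k, alphabet, stats::setNames(numeric(0), character(0)), 0))
  r <- rle(sort(codes))
  counts <- as.numeric(r$lengths)
  names(counts) <- .decode_codes(r$values, k, alphabet)
  .new_count_table(k, alphabet, counts, total)
}

#' Build a k-mer count table from explicit counts
#'
#' Constructor for small, fully specified tables (examples, tests, oracles).
#'
#' @param counts Named numeric vector of non-negative counts; names are k-mers
#'   of a common length over `alphabet`. Zero entries are dropped (nullomers).
#' @param alphabet Alphabet of the k-mer symbols.
#' @return A `kmer_count_table`.
#' @examples
#' kmer_count_table(c(AC = 2, CG = 2, GT = 2))
#' @export
kmer_count_table <- function(counts, alphabet = nt_alphabet()) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  k <- unique(nchar(names(counts)))
  if (length(k) != 1L)
    .ks_stop("all k-mer names must share one length", "ks_invalid_request")
  counts <- counts[counts > 0]
  codes <- .encode_kmers(names(counts), k, alphabet)
  if (anyNA(codes))
    .ks_stop("k-mer names contain symbols outside the alphabet",
             "ks_invalid_request")
  o <- order(codes)
  .new_count_table(k, alphabet, counts[o], sum(counts))
}

#' Uniform k-mer count table
#'
#' Dense table in which every one of the `A^k` possible k-mers occurs exactly
#' `count` times; the reference distribution attaining maximal entropy.
#'
#' @inheritParams count_kmers
#' @param count Occurrences per k-mer.
#' @export
uniform_count_table <- function(alphabet = nt_alphabet(), k, count = 1) {
  stopifnot(k >= 1L, count > 0)
  nk <- alphabet$size^k
  if (nk > 2^26)
    .ks_stop("uniform table too large to materialise; use max_entropy()",
             "ks_invalid_request")
  .new_count_table(k, alphabet, rep(as.numeric(count), nk), count * nk,
                   dense = TRUE)
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("<kmer_count_table> k=%d alphabet=%s observed=%d total=%s%s\n",
              x$k, x$alphabet$name, sum(x$counts > 0),
              format(x$total, big.mark = ","),
              if (x$dense) " (dense)" else ""))
  invisible(x)
}

# Observed (count > 0) entries: list(codes, kmers(optional), counts).
.observed <- function(table, want_names = TRUE) {
  if (table$dense) {
    idx <- which(table$counts > 0)
    list(counts = table$counts[idx],
         kmers = if (want_names) .decode_codes(idx - 1, table$k, table$alphabet))
  } else {
    list(counts = unname(table$counts),
         kmers = if (want_names) names(table$counts))
  }
}

# ---- information statistics -------------------------------------------------

#' k-mer probability
#'
#' Maximum-likelihood probability of a k-mer: its count divided by the total
#' number of accepted windows. Nullomers have probability 0.
#'
#' @param table A `kmer_count_table`.
#' @param kmer Character vector of k-mers (length `table$k`).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
kmer_probability <- function(table, kmer) {
  if (table$total <= 0)
    .ks_stop("empty table: the k-mer distribution is undefined",
             "ks_undefined_distribution")
  codes <- .encode_kmers(toupper(kmer), table$k, table$alphabet)
  if (anyNA(codes))
    .ks_stop("k-mer contains symbols outside the table's alphabet",
             "ks_invalid_request")
  cnt <- if (table$dense) {
    table$counts[codes + 1]
  } else {
    v <- table$counts[match(toupper(kmer), names(table$counts))]
    v[is.na(v)] <- 0
    v
  }
  unname(cnt) / table$total
}

#' k-mer surprisal
#'
#' Self-information of a k-mer, `-log2(p)`, in bits. The surprisal of a
#' nullomer (p = 0) is undefined and raises a classed error rather than
#' returning an infinite sentinel, so callers must handle it explicitly.
#'
#' @inheritParams kmer_probability
#' @return Numeric vector of surprisals in bits; exactly 0 where p = 1.
#' @export
kmer_surprisal <- function(table, kmer) {
  p <- kmer_probability(table, kmer)
  if (any(p == 0))
    .ks_stop(sprintf("surprisal undefined for nullomer(s): %s",
                     paste(utils::head(kmer[p == 0], 5), collapse = ", ")),
             "ks_undefined_surprisal")
  ifelse(p == 1, 0, -log2(p))
}

#' Shannon entropy of a k-mer distribution
#'
#' Expected surprisal over the observed k-mer ensemble, in bits. Unobserved
#' k-mers contribute 0 (the 0 log 0 limit).
#'
#' @param table A `kmer_count_table` with `total > 0`.
#' @return Entropy in bits, in \[0, [max_entropy()]\].
#' @export
kmer_entropy <- function(table) {
  if (table$total <= 0)
    .ks_stop("empty table: entropy is undefined", "ks_undefined_distribution")
  cnt <- .observed(table, want_names = FALSE)$counts
  p <- cnt / table$total
  -sum(p * log2(p))
}

#' Maximum entropy of an alphabet at word length k
#'
#' `k * log2(A)` bits: 2k for nucleotides, k*log2(20) for amino acids.
#'
#' @param alphabet A `kmer_alphabet`.
#' @param k Word length (>= 0).
#' @export
max_entropy <- function(alphabet, k) {
  stopifnot(k >= 0)
  k * log2(alphabet$size)
}

#' Entropy, redundancy and total information of a k-mer table
#'
#' Summarises the information content of a k-mer distribution: the observed
#' entropy `h_obs`, the alphabet ceiling `h_max = k log2(A)`, the redundancy
#' `R = 1 - h_obs / h_max` (information capacity left unrealised by nullomers
#' and distributional skew), the total information `I = sum counts(x) S(x) =
#' total * h_obs`, and saturation diagnostics (`n_observed`,
#' `fraction_observed = n_observed / A^k`).
#'
#' @param table A `kmer_count_table` with `total > 0`.
#' @return An `entropy_summary` list.
#' @export
entropy_summary <- function(table) {
  h_obs <- kmer_entropy(table)
  h_max <- max_entropy(table$alphabet, table$k)
  obs <- .observed(table, want_names = FALSE)
  structure(list(
    k = table$k,
    alphabet = table$alphabet$name,
    h_obs = h_obs,
    h_max = h_max,
    redundancy = 1 - h_obs / h_max,
    total_information = table$total * h_obs,
    n_observed = length(obs$counts),
    fraction_observed = length(obs$counts) / table$alphabet$size^table$k,
    total = table$total
  ), class = "entropy_summary")
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf(
    "<entropy_summary> k=%d (%s)\n  H_obs=%.4f bits  H_max=%.4f bits  R=%.4f\n  I=%.4g bits over %s windows; %d k-mers observed (fraction %.3g)\n",
    x$k, x$alphabet, x$h_obs, x$h_max, x$redundancy, x$total_information,
    format(x$total, big.mark = ","), x$n_observed, x$fraction_observed))
  invisible(x)
}

#' Occurrence spectrum of a k-mer table
#'
#' For each occurrence count c, the number of distinct observed k-mers that
#' occur exactly c times. Nullomers are excluded.
#'
#' @param table A `kmer_count_table`.
#' @return Data frame with columns `occurrences` and `n_kmers`, ascending.
#' @export
kmer_spectrum <- function(table) {
  cnt <- .observed(table, want_names = FALSE)$counts
  if (!length(cnt))
    return(data.frame(occurrences = numeric(0), n_kmers = integer(0)))
  r <- rle(sort(cnt))
  data.frame(occurrences = r$values, n_kmers = r$lengths)
}

#' Redundancy and saturation across a range of k
#'
#' Counts k-mers at each k in `k_range` and reports the redundancy and the
#' fraction of all possible k-mers observed at least once. Rows where the
#' number of possible k-mers `A^k` exceeds the number of counted windows are
#' flagged `truncated`: there the fraction observed is bounded above by
#' `total / A^k` by pigeonhole and the redundancy rise is a finite-sample
#' artefact rather than a property of the sequence.
#'
#' @inheritParams count_kmers
#' @param k_range Integer vector of k values.
#' @return Data frame with one row per k: `k`, `total`, `n_observed`,
#'   `h_obs`, `h_max`, `redundancy`, `fraction_observed`, `truncated`.
#' @export
k_selection_report <- function(sequences, alphabet = nt_alphabet(),
                               k_range = 2:15, both_strands = FALSE) {
  rows <- lapply(as.integer(k_range), function(k) {
    tab <- count_kmers(sequences, k, alphabet, both_strands)
    if (tab$total == 0)
      return(data.frame(k = k, total = 0, n_observed = 0L, h_obs = NA_real_,
                        h_max = max_entropy(alphabet, k), redundancy = NA_real_,
                        fraction_observed = 0, truncated = TRUE))
    es <- entropy_summary(tab)
    data.frame(k = k, total = tab$total, n_observed = es$n_observed,
               h_obs = es$h_obs, h_max = es$h_max, redundancy = es$redundancy,
               fraction_observed = es$fraction_observed,
               truncated = alphabet$size^k > tab$total)
  })
  do.call(rbind, rows)
}

#' Smallest k at which an alphabet saturates a sequence
#'
#' The smallest k for which the number of possible k-mers `A^k` exceeds the
#' number of available k-mer positions, i.e. the resolution beyond which not
#' every k-mer can be observed even in principle.
#'
#' @param n_positions Total number of k-mer windows available.
#' @param alphabet A `kmer_alphabet`.
#' @export
saturation_k <- function(n_positions, alphabet = nt_alphabet()) {
  stopifnot(n_positions >= 1)
  k <- 1L
  while (alphabet$size^k <= n_positions) k <- k + 1L
  k
}

# ---- surprisal lookup tables ------------------------------------------------

#' Surprisal lookup table
#'
#' Precomputes `-log2(counts/total)` for every observed k-mer of a count
#' table, for fast vectorised lookup in profile computations. Nullomers map
#' to `NA` on lookup, which profile aggregation treats as "excluded", in
#' contrast to the strict error semantics of [kmer_surprisal()].
#'
#' @param table A `kmer_count_table` with `total > 0`.
#' @return A `surprisal_table` object.
#' @export
surprisal_table <- function(table) {
  if (table$total <= 0)
    .ks_stop("empty table: surprisal is undefined", "ks_undefined_distribution")
  A <- table$alphabet$size
  nk <- A^table$k
  if (table$dense) {
    vals <- rep(NA_real_, nk)
    idx <- which(table$counts > 0)
    vals[idx] <- -log2(table$counts[idx] / table$total)
    dense <- TRUE
  } else if (nk <= 2^24) {
    vals <- rep(NA_real_, nk)
    codes <- .encode_kmers(names(table$counts), table$k, table$alphabet)
    vals[codes + 1] <- -log2(table$counts / table$total)
    dense <- TRUE
  } else {
    vals <- -log2(table$counts / table$total)
    dense <- FALSE
  }
  structure(list(k = table$k, alphabet = table$alphabet, values = vals,
                 dense = dense, total = table$total),
            class = "surprisal_table")
}

#' Look up surprisals for a vector of k-mers
#'
#' @param st A [surprisal_table()].
#' @param kmers Character vector; entries with foreign symbols or that are
#'   nullomers in the source table yield `NA`.
#' @return Numeric vector of surprisals in bits (NA where undefined).
#' @export
surprisal_lookup <- function(st, kmers) {
  if (!length(kmers)) return(numeric(0))
  if (st$dense) {
    m <- matrix(match(unlist(strsplit(kmers, NULL)), st$alphabet$symbols),
                nrow = st$k)
    pw <- st$alphabet$size^((st$k - 1L):0L)
    codes <- colSums((m - 1) * pw)
    out <- rep(NA_real_, length(kmers))
    okc <- !is.na(codes)
    out[okc] <- st$values[codes[okc] + 1]
    out
  } else {
    unname(st$values[match(kmers, names(st$values))])
  }
}

#' @export
print.surprisal_table <- function(x, ...) {
  cat(sprintf("<surprisal_table> k=%d alphabet=%s total=%s%s\n",
              x$k, x$alphabet$name, format(x$total, big.mark = ","),
              if (x$dense) " (dense lookup)" else ""))
  invisible(x)
}

# ---- IO ---------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Multi-record, wrapped-line FASTA; names are truncated at the first
#' whitespace (Ensembl headers carry description fields).
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path))
    .ks_stop(paste0("FASTA file not found: ", path), "ks_io_error")
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as.character(x)
}

#' @rdname read_genome_fasta
#' @export
read_peptide_fasta <- function(path) {
  if (!file.exists(path))
    .ks_stop(paste0("FASTA file not found: ", path), "ks_io_error")
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as.character(x)
}

#' Write a k-mer frequency table as TSV
#'
#' Columns `kmer`, `count`, `probability`, `surprisal_bits`; observed k-mers
#' only, in lexicographic order for reproducible output.
#'
#' @param table A `kmer_count_table`.
#' @param path Output path.
#' @param comments Optional `# `-prefixed header lines.
#' @export
write_count_table <- function(table, path, comments = character(0)) {
  obs <- .observed(table)
  o <- order(obs$kmers)
  p <- obs$counts[o] / table$total
  .write_tsv(data.frame(kmer = obs$kmers[o], count = obs$counts[o],
                        probability = p, surprisal_bits = -log2(p)),
             path, comments)
}
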