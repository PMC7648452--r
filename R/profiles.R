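# Junction-anchored surprisal profiles.
#
# Anchoring convention, used everywhere: offset 0 is the first position
# downstream of the junction in transcript orientation, offset -1 the last
# position upstream, so the junction falls between offsets -1 and 0.  The
# value plotted at offset i is the surprisal of the k-mer whose FIRST symbol
# sits at offset i; the k-mer at offset -1 of an exon-exon junction therefore
# joins the last exon base to the next k-1 bases across the splice.

#' Extract junction-anchored sequence windows
#'
#' For donor/acceptor junctions the window is read from the genomic sequence
#' on the transcript strand; for exon-exon junctions (and their coding-mRNA /
#' amino-acid analogues) it is read from the supplied spliced sequences. The
#' window covers offsets `[-upstream, downstream)`. Positions beyond the ends
#' of the source sequence are padded with `"."`, which marks the window
#' truncated there: k-mers touching padding are excluded from the affected
#' offsets only, not the whole junction.
#'
#' @param junctions Data frame from [derive_junctions()] (or with compatible
#'   columns).
#' @param genome Named contig sequences; required for genomic-anchored kinds.
#' @param seqs Named per-transcript sequences (spliced, CDS, or peptide),
#'   indexed by `transcript_id`; required for spliced-anchored kinds.
#' @param upstream,downstream Window extents (symbols).
#' @param anchor_col Column holding the anchor for spliced-anchored kinds;
#'   default `"spliced_pos"` (use `"cds_pos"` with CDS sequences, or a
#'   residue-scale column with peptides).
#' @return Character vector of windows (length `upstream + downstream`), with
#'   attributes `upstream`, `downstream` and `truncated` (logical).
#' @export
junction_windows <- function(junctions, genome = NULL, seqs = NULL,
                             upstream = 100L, downstream = 100L,
                             anchor_col = "spliced_pos") {
  U <- as.integer(upstream); D <- as.integer(downstream)
  stopifnot(U >= 1L, D >= 1L)
  n <- nrow(junctions)
  out <- character(n)
  for (i in seq_len(n)) {
    kind <- junctions$kind[i]
    if (kind %in% c("donor", "acceptor")) {
      if (is.null(genome))
        .ks_stop("genome required for donor/acceptor windows",
                 "ks_invalid_request")
      chrom <- junctions$chrom[i]
      if (!chrom %in% names(genome))
        .ks_stop(paste0("contig not in genome: ", chrom), "ks_coordinate_error")
      s <- genome[[chrom]]
      a <- junctions$anchor[i]
      if (junctions$strand[i] == "+") {
        out[i] <- .padded_slice(s, a - U, a + D)
      } else {
        out[i] <- .revcomp_chr(.padded_slice(s, a - D + 1L, a + U + 1L))
      }
    } else {
      if (is.null(seqs))
        .ks_stop("per-transcript sequences required for spliced windows",
                 "ks_invalid_request")
      tid <- junctions$transcript_id[i]
      if (!tid %in% names(seqs))
        .ks_stop(paste0("transcript not in seqs: ", tid), "ks_coordinate_error")
      a <- junctions[[anchor_col]][i]
      if (is.na(a))
        .ks_stop("junction lacks an anchor in the requested coordinate space",
                 "ks_coordinate_error")
      out[i] <- .padded_slice(seqs[[tid]], a - U, a + D)
    }
  }
  out <- toupper(out)
  structure(out, upstream = U, downstream = D,
            truncated = grepl(".", out, fixed = TRUE))
}

# Per-offset summary of a junctions x offsets value matrix.
.summarize_profile <- function(M, offsets) {
  n <- colSums(!is.na(M))
  mu <- suppressWarnings(colMeans(M, na.rm = TRUE))
  mu[n == 0L] <- NA_real_
  sdv <- apply(M, 2, stats::sd, na.rm = TRUE)
  sdv[n < 2L] <- NA_real_
  cv <- ifelse(!is.na(mu) & mu != 0, sdv / mu, NA_real_)
  data.frame(offset = offsets, n = n, mean_surprisal = mu, sd = sdv, cv = cv,
             n_excluded = nrow(M) - n)
}

.new_profile <- function(values, offsets, k) {
  structure(list(stats = .summarize_profile(values, offsets),
                 values = values, offsets = offsets, k = k),
            class = "junction_profile")
}

#' Junction-anchored mean surprisal profile
#'
#' Scores, at every offset i in the window, the k-mer starting at i of each
#' junction window against a [surprisal_table()], and summarises across
#' junctions per offset (n, mean, sd, cv). k-mers containing foreign or
#' padding symbols, and k-mers that are nullomers in the table, are excluded
#' from that offset's n (the exclusion count is reported).
#'
#' @param windows Output of [junction_windows()].
#' @param st A [surprisal_table()] whose k and alphabet match the windows'
#'   sequence space.
#' @return A `junction_profile`: `$stats` (per-offset data frame), `$values`
#'   (junctions x offsets surprisal matrix), `$offsets`, `$k`.
#' @export
profile_surprisal <- function(windows, st) {
  U <- attr(windows, "upstream"); D <- attr(windows, "downstream")
  if (is.null(U) || is.null(D))
    .ks_stop("windows must come from junction_windows()", "ks_invalid_request")
  k <- st$k
  if (U + D < k)
    .ks_stop("window narrower than k", "ks_invalid_request")
  offsets <- seq.int(-U, D - k)
  M <- matrix(NA_real_, length(windows), length(offsets))
  w <- as.character(windows)
  for (j in seq_along(offsets)) {
    M[, j] <- surprisal_lookup(st, substr(w, j, j + k - 1L))
  }
  .new_profile(M, offsets, k)
}

#' @export
print.junction_profile <- function(x, ...) {
  cat(sprintf("<junction_profile> k=%d, %d junctions, offsets %d..%d\n",
              x$k, nrow(x$values), min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Expand an amino-acid profile onto nucleotide offsets
#'
#' Amino-acid k-mers are a third the length of the nucleotide k-mers they are
#' compared with (`k_aa = k_nt / 3`). To overlay the spaces, each junction's
#' amino-acid surprisal values are repeated over the 3 nucleotide offsets of
#' their first codon, shifted by that junction's codon phase (the junction's
#' CDS offset mod 3), and per-nucleotide-offset averaging then proceeds as
#' usual. An amino-acid k-mer at residue offset a of a phase-ph junction
#' covers nucleotide offsets `3a - ph + 0:2`.
#'
#' @param aa_profile A `junction_profile` computed on peptide windows.
#' @param phases Integer vector (0, 1 or 2), one per junction row of the
#'   profile.
#' @param k_nt Nucleotide k; must equal `3 * aa_profile$k`.
#' @return A `junction_profile` on nucleotide offsets.
#' @export
aa_profile_expand <- function(aa_profile, phases, k_nt) {
  if (k_nt %% 3L != 0L || k_nt != 3L * aa_profile$k)
    .ks_stop("k_nt must be 3 * k_aa (amino-acid comparison requires k_nt divisible by 3)",
             "ks_invalid_request")
  nj <- nrow(aa_profile$values)
  if (length(phases) != nj)
    .ks_stop("one phase per junction required", "ks_invalid_request")
  if (any(!phases %in% 0:2))
    .ks_stop("phases must be 0, 1 or 2", "ks_invalid_request")
  ao <- aa_profile$offsets
  nt_offsets <- seq.int(3L * min(ao) - 2L, 3L * max(ao) + 2L)
  N <- matrix(NA_real_, nj, length(nt_offsets))
  for (ph in unique(phases)) {
    rows <- which(phases == ph)
    for (j in seq_along(ao)) {
      base <- 3L * ao[j] - ph
      cols <- match(base + 0:2, nt_offsets)
      for (d in 1:3) N[rows, cols[d]] <- aa_profile$values[rows, j]
    }
  }
  .new_profile(N, nt_offsets, as.integer(k_nt))
}

#' Per-offset coefficient of variation of a profile
#'
#' The standard cv = sd/mean is reported under the primary name; the inverted
#' ratio mean/sd is also emitted (`mean_over_sd`) for comparison with
#' conventions that print it that way. Offsets with fewer than 2 junctions or
#' zero mean are undefined (NA).
#'
#' @param profile A `junction_profile`.
#' @return Data frame `offset`, `cv`, `mean_over_sd`, `n`.
#' @export
coefficient_of_variation <- function(profile) {
  s <- profile$stats
  cv <- ifelse(s$n >= 2L & !is.na(s$mean_surprisal) & s$mean_surprisal != 0,
               s$sd / s$mean_surprisal, NA_real_)
  data.frame(offset = s$offset, cv = cv,
             mean_over_sd = ifelse(!is.na(cv) & s$sd > 0,
                                   s$mean_surprisal / s$sd, NA_real_),
             n = s$n)
}

#' Per-offset dinucleotide frequency across junction windows
#'
#' Fraction of junctions whose dinucleotide starting at offset i equals the
#' query, among junctions with a valid (unpadded, alphabet-complete)
#' dinucleotide at that offset.
#'
#' @param windows Output of [junction_windows()] (nucleotide space).
#' @param dinucleotide Two-letter query, e.g. `"CG"`.
#' @return Data frame `offset`, `frequency`, `n_valid`.
#' @export
positional_dinucleotide_frequency <- function(windows, dinucleotide) {
  stopifnot(nchar(dinucleotide) == 2L)
  U <- attr(windows, "upstream"); D <- attr(windows, "downstream")
  offsets <- seq.int(-U, D - 2L)
  w <- as.character(windows)
  freq <- numeric(length(offsets))
  nv <- integer(length(offsets))
  for (j in seq_along(offsets)) {
    dn <- substr(w, j, j + 1L)
    valid <- grepl("^[ACGT]{2}$", dn)
    nv[j] <- sum(valid)
    freq[j] <- if (nv[j]) sum(dn[valid] == dinucleotide) / nv[j] else NA_real_
  }
  data.frame(offset = offsets, frequency = freq, n_valid = nv)
}

#' Write a junction profile as TSV
#'
#' Columns `space`, `k`, `offset`, `n`, `mean_surprisal_bits`, `sd`, `cv`.
#'
#' @param profile A `junction_profile`.
#' @param path Output path.
#' @param space Label for the sequence space (`"dna"`, `"coding_mrna"`,
#'   `"amino_acid"`).
#' @param comments Optional header comment lines.
#' @export
write_profile <- function(profile, path, space = "dna",
                          comments = character(0)) {
  s <- profile$stats
  .write_tsv(data.frame(space = space, k = profile$k, offset = s$offset,
                        n = s$n, mean_surprisal_bits = s$mean_surprisal,
                        sd = s$sd, cv = s$cv),
             path, comments)
}
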