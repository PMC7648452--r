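# Internal helpers shared across modules.

# Signal a classed error so callers can distinguish failure modes
# (invalid request, undefined distribution, coordinate error, ...).
.ks_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ks_error")))
}

# Reverse complement for clean nucleotide sequences (ACGTN + IUPAC).
.revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse complement tolerant of window padding characters ("."): anything
# outside the complement map is passed through unchanged.
.revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Coerce FASTA-ish inputs (XStringSet or character) to an uppercase named
# character vector.
.as_char_seqs <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) .ks_stop("sequences must be a character vector or XStringSet",
                                 "ks_invalid_request")
  toupper(x)
}

# Substring of a 0-based half-open slice, padded with "." where the slice
# extends past the sequence ends; padding marks positions with no data so
# downstream k-mer extraction skips them.
.padded_slice <- function(s, from, to) {
  n <- nchar(s)
  a <- max(from, 0L)
  b <- min(to, n)
  core <- if (b > a) substr(s, a + 1L, b) else ""
  paste0(strrep(".", max(0L, a - from)), core, strrep(".", max(0L, to - b)))
}

# Run expr with a private RNG state, restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Write a data frame as a deterministic TSV, optionally preceded by "# "
# comment lines (used by the CLI for provenance headers).
.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
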