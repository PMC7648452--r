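#' Sequence alphabets
#'
#' A `kmer_alphabet` fixes the symbol set over which k-mers are formed. Two
#' alphabets are used throughout: the nucleotide alphabet \{A, C, G, T\} and
#' the 20 standard amino-acid one-letter codes. Any window containing a symbol
#' outside the alphabet (an N, an ambiguity code, a stop `*`) is discarded
#' whole rather than truncated.
#'
#' @return A `kmer_alphabet` object with fields `name`, `symbols` (ordered,
#'   unique, single characters) and `size`.
#' @examples
#' nt_alphabet()
#' aa_alphabet()$size
#' @export
nt_alphabet <- function() {
  .new_alphabet("nucleotide", c("A", "C", "G", "T"))
}

#' @rdname nt_alphabet
#' @export
aa_alphabet <- function() {
  .new_alphabet("amino_acid", strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]])
}

.new_alphabet <- function(name, symbols) {
  stopifnot(is.character(symbols), all(nchar(symbols) == 1L),
            !anyDuplicated(symbols))
  structure(list(name = name, symbols = symbols, size = length(symbols)),
            class = "kmer_alphabet")
}

#' @export
print.kmer_alphabet <- function(x, ...) {
  cat(sprintf("<kmer_alphabet> %s (%d symbols): %s\n",
              x$name, x$size, paste(x$symbols, collapse = "")))
  invisible(x)
}
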