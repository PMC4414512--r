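#' IUPAC nucleotide utilities
#'
#' Small helpers shared across the package: sequence validation,
#' reverse-complement, and IUPAC-aware base compatibility. Two letters are
#' compatible when the base sets they denote intersect, so an ambiguity code
#' in a primer matches any base it covers and never counts as a mismatch.
#'
#' @name iupac
#' @keywords internal
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Validate a DNA string
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @param allow_iupac allow ambiguity codes beyond A/C/G/T/N.
#' @return the validated, upper-cased string.
#' @keywords internal
check_dna <- function(x, what = "sequence", allow_iupac = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  x <- toupper(x)
  ok <- if (allow_iupac) IUPAC_LETTERS else c("A", "C", "G", "T", "N")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% ok)
  if (length(bad))
    stop(what, " contains non-DNA character '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  x
}

#' Reverse-complement of DNA strings (IUPAC-aware)
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTR")
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' IUPAC-aware mismatch count between a pattern and sequence ends
#'
#' Counts positions where the pattern letter's base set does not intersect
#' the sequence letter's base set, comparing the pattern against the prefix
#' (or suffix) of each sequence. Sequences shorter than the pattern give NA.
#'
#' @param seqs character vector of sequences.
#' @param pattern single pattern string (may contain ambiguity codes).
#' @param from_end compare against the suffix instead of the prefix.
#' @return integer vector of mismatch counts.
#' @keywords internal
iupac_mismatch <- function(seqs, pattern, from_end = FALSE) {
  .pattern_mismatch(as.character(seqs), toupper(pattern), isTRUE(from_end))
}

#' Decode a Phred+33 quality string to integer scores
#' @keywords internal
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a +33 string
#' @keywords internal
phred_encode <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1L))
}
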