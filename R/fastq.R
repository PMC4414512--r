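#' FASTQ input/output
#'
#' Reads are carried through the pipeline as a plain data.frame with columns
#' `read_id`, `sequence` and `qualities` (Sanger Phred+33). I/O goes through
#' Biostrings.
#'
#' @param path FASTQ file.
#' @return `read_fastq()`: the read data.frame; `write_fastq()`: the path.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads read data.frame.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$qualities)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$qualities))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
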