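#' Universal primer pairs
#'
#' A primer pair holds the two oligos as synthesized (both written 5'->3';
#' the reverse primer is therefore the reverse complement of the template top
#' strand), the annealing temperature, and the expected full amplicon length
#' range (primers included) across the species the pair was designed for.
#'
#' @param name short unique identifier, e.g. `"12S_KH"`.
#' @param forward,reverse primer sequences 5'->3' (IUPAC codes allowed).
#' @param annealing_temp annealing temperature in degrees C (metadata).
#' @param len_range inclusive `c(min, max)` of the full amplicon length in bp,
#'   or `c(NA, NA)` when unknown.
#' @return an object of class `primer_pair`.
#' @export
#' @examples
#' primer_pair("toy", "ACGTACGT", "TTGGCCAA", 55, c(60, 80))
primer_pair <- function(name, forward, reverse, annealing_temp = NA_real_,
                        len_range = c(NA_integer_, NA_integer_)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  forward <- check_dna(forward, paste0("forward primer of ", name))
  reverse <- check_dna(reverse, paste0("reverse primer of ", name))
  if (length(len_range) != 2L)
    stop("len_range must have length 2", call. = FALSE)
  len_range <- as.integer(len_range)
  if (!anyNA(len_range) && len_range[1L] > len_range[2L])
    stop("len_range min exceeds max for pair ", name, call. = FALSE)
  structure(list(name = name, forward = forward, reverse = reverse,
                 annealing_temp = as.numeric(annealing_temp),
                 len_range = len_range),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Primer pair", x$name, "\n")
  cat("  forward:", x$forward, sprintf("(%d nt)", nchar(x$forward)), "\n")
  cat("  reverse:", x$reverse, sprintf("(%d nt)", nchar(x$reverse)), "\n")
  if (!is.na(x$annealing_temp))
    cat("  annealing:", x$annealing_temp, "degC\n")
  if (!anyNA(x$len_range))
    cat("  amplicon:", x$len_range[1L], "-", x$len_range[2L], "bp\n")
  invisible(x)
}

#' Assemble a primer set
#'
#' @param ... `primer_pair` objects (or one list of them).
#' @return named list of `primer_pair` objects, class `primer_set`.
#' @export
primer_set <- function(...) {
  pairs <- list(...)
  if (length(pairs) == 1L && !inherits(pairs[[1L]], "primer_pair"))
    pairs <- pairs[[1L]]
  if (!length(pairs) || !all(vapply(pairs, inherits, logical(1L), "primer_pair")))
    stop("primer_set() takes one or more primer_pair objects", call. = FALSE)
  nms <- vapply(pairs, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate primer pair name: ", nms[duplicated(nms)][1L], call. = FALSE)
  names(pairs) <- nms
  structure(pairs, class = "primer_set")
}

#' The three universal 12S/16S rRNA primer pairs for meat species work
#'
#' Two pairs target the mitochondrial 12S and 16S rRNA genes using primers
#' designed on large mammalian alignments (`12S_KH`, `16S_KH`), and a third
#' 16S pair designed on a smaller mammalian alignment and validated across
#' vertebrate classes (`16S_Ki`). Amplicon length ranges are the full-product
#' sizes observed across the 13 study species (primers included).
#'
#' @return a `primer_set` of three `primer_pair` objects.
#' @export
#' @examples
#' meat_primer_pairs()[["12S_KH"]]
meat_primer_pairs <- function() {
  primer_set(
    primer_pair("12S_KH", "CCCAAACTGGGATTAGATACCC", "GTTTGCTGAAGATGGCGGTA",
                59, c(215L, 222L)),
    primer_pair("16S_KH", "GACGAGAAGACCCTATGGAGC", "TCCGAGGTCGCCCCAACC",
                59, c(112L, 121L)),
    primer_pair("16S_Ki", "GCCTGTTTACCAAAAACATCAC", "CTCCATAGGGTCTTCTCGTCTT",
                62, c(243L, 249L))
  )
}

#' Read or write a primer set as TSV
#'
#' Columns: name, forward, reverse, annealing_temp, min_len, max_len.
#'
#' @param path file path.
#' @param pairs a `primer_set`.
#' @return `read_primers()` returns a `primer_set`; `write_primers()` the path.
#' @export
read_primers <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse")
  if (!all(need %in% names(df)))
    stop("primer TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$annealing_temp)) df$annealing_temp <- NA_real_
  if (is.null(df$min_len)) df$min_len <- NA_integer_
  if (is.null(df$max_len)) df$max_len <- NA_integer_
  primer_set(lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$name[i], df$forward[i], df$reverse[i],
                df$annealing_temp[i], c(df$min_len[i], df$max_len[i]))))
}

#' @rdname read_primers
#' @export
write_primers <- function(pairs, path) {
  stopifnot(inherits(pairs, "primer_set"))
  df <- data.frame(
    name = vapply(pairs, `[[`, character(1L), "name"),
    forward = vapply(pairs, `[[`, character(1L), "forward"),
    reverse = vapply(pairs, `[[`, character(1L), "reverse"),
    annealing_temp = vapply(pairs, `[[`, numeric(1L), "annealing_temp"),
    min_len = vapply(pairs, function(p) p$len_range[1L], integer(1L)),
    max_len = vapply(pairs, function(p) p$len_range[2L], integer(1L)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
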