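#' Demultiplex reads by 5' barcode
#'
#' Assigns each read to the unique barcode whose sequence matches the read's
#' 5' end within `max_mismatch` and clips it. Reads matching no barcode, or
#' more than one within tolerance, go to the unassigned bin. The barcode set
#' must be unambiguous: equal lengths and pairwise Hamming distance greater
#' than `2 * max_mismatch`.
#'
#' @param reads read data.frame (`read_id`, `sequence`, `qualities`).
#' @param barcode_map named character vector, label -> barcode sequence.
#' @param max_mismatch per-barcode mismatch tolerance.
#' @return list with `bins` (named list of read data.frames, barcode
#'   clipped) and `unassigned` (read data.frame).
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 1L) {
  if (!is.character(barcode_map) || is.null(names(barcode_map)))
    stop("barcode_map must be a named character vector", call. = FALSE)
  bl <- nchar(barcode_map)
  if (length(unique(bl)) != 1L)
    stop("barcodes must all have the same length", call. = FALSE)
  if (length(barcode_map) > 1L) {
    for (i in seq_len(length(barcode_map) - 1L))
      for (j in (i + 1L):length(barcode_map)) {
        d <- iupac_mismatch(barcode_map[i], barcode_map[j])
        if (d <= 2L * max_mismatch)
          stop("barcodes ", names(barcode_map)[i], " and ",
               names(barcode_map)[j], " are only ", d,
               " mismatches apart; need > ", 2L * max_mismatch,
               call. = FALSE)
      }
  }
  if (!nrow(reads))
    return(list(bins = setNames(rep(list(reads), length(barcode_map)),
                                names(barcode_map)), unassigned = reads))
  dm <- vapply(barcode_map, function(bc) iupac_mismatch(reads$sequence, bc),
               integer(nrow(reads)))
  dm <- matrix(dm, nrow = nrow(reads))
  ok <- !is.na(dm) & dm <= max_mismatch
  nhit <- rowSums(ok)
  bins <- list()
  for (b in seq_along(barcode_map)) {
    sel <- nhit == 1L & ok[, b]
    sub <- reads[sel, , drop = FALSE]
    sub$sequence <- substring(sub$sequence, bl[1L] + 1L)
    sub$qualities <- substring(sub$qualities, bl[1L] + 1L)
    rownames(sub) <- NULL
    bins[[names(barcode_map)[b]]] <- sub
  }
  una <- reads[nhit != 1L, , drop = FALSE]
  rownames(una) <- NULL
  list(bins = bins, unassigned = una)
}

#' Trim primer sequences from both read ends
#'
#' For every primer pair and both read orientations, compares the 5' end of
#' the read against the pair's entry primer and the 3' end against the
#' reverse complement of its partner (Hamming comparison, no indels inside
#' the primer match). The best-supported candidate (most ends matched, then
#' fewest mismatches) is clipped; each end is clipped independently, so a
#' read truncated before the 3' primer still loses its 5' primer. Reads
#' matching no primer pass through flagged untrimmed. Qualities are clipped
#' in register. Trimming is idempotent.
#'
#' @param reads read data.frame.
#' @param pairs a [primer_set()].
#' @param max_mismatch per-primer mismatch tolerance.
#' @return the read data.frame plus columns `pair` (matched pair name or
#'   NA), `orientation` (`"+"` read starts with the forward primer, `"-"`
#'   with the reverse), `trimmed_fwd`, `trimmed_rev` (logical: 5'/3' end
#'   clipped).
#' @export
trim_primers <- function(reads, pairs, max_mismatch = 2L) {
  stopifnot(inherits(pairs, "primer_set"))
  n <- nrow(reads)
  out <- reads
  out$pair <- NA_character_
  out$orientation <- NA_character_
  out$trimmed_fwd <- logical(n)
  out$trimmed_rev <- logical(n)
  if (!n) return(out)
  cand <- list()
  for (p in pairs) {
    cand[[paste0(p$name, "|+")]] <-
      list(pair = p$name, orientation = "+", five = p$forward,
           three = revcomp(p$reverse))
    cand[[paste0(p$name, "|-")]] <-
      list(pair = p$name, orientation = "-", five = p$reverse,
           three = revcomp(p$forward))
  }
  mm5 <- vapply(cand, function(cc) iupac_mismatch(reads$sequence, cc$five),
                integer(n))
  mm3 <- vapply(cand, function(cc)
    iupac_mismatch(reads$sequence, cc$three, from_end = TRUE), integer(n))
  mm5 <- matrix(mm5, nrow = n); mm3 <- matrix(mm3, nrow = n)
  ok5 <- !is.na(mm5) & mm5 <= max_mismatch
  ok3 <- !is.na(mm3) & mm3 <= max_mismatch
  ends <- ok5 + ok3
  cost <- ifelse(ok5, mm5, 0L) + ifelse(ok3, mm3, 0L)
  # candidate order breaks remaining ties: pairs in set order, "+" first
  rank <- ends * 1000L - cost
  pick <- max.col(rank, ties.method = "first")
  any_end <- ends[cbind(seq_len(n), pick)] > 0L
  for (i in which(any_end)) {
    cc <- cand[[pick[i]]]
    s <- out$sequence[i]; q <- out$qualities[i]
    len <- nchar(s)
    c5 <- ok5[i, pick[i]]; c3 <- ok3[i, pick[i]]
    n5 <- if (c5) nchar(cc$five) else 0L
    n3 <- if (c3) nchar(cc$three) else 0L
    if (len - n5 - n3 < 1L) { n3 <- 0L; c3 <- FALSE }  # degenerate short read
    out$sequence[i] <- substr(s, n5 + 1L, len - n3)
    out$qualities[i] <- substr(q, n5 + 1L, len - n3)
    out$pair[i] <- cc$pair
    out$orientation[i] <- cc$orientation
    out$trimmed_fwd[i] <- c5
    out$trimmed_rev[i] <- c3
  }
  out
}

#' Run-level quality statistics
#'
#' Counts called nucleotides and those at Phred >= `q` (Q20 by default);
#' the Q20 percentage is reported rounded to 2 decimals via
#' [q20_percent()]. Pass the result of [demultiplex()] to get a per-barcode
#' breakdown.
#'
#' @param reads a read data.frame, or a [demultiplex()] result.
#' @param q Phred threshold (inclusive).
#' @return list with `n_reads`, `called_nt`, `q20_nt`, `q20_pct`, and
#'   `per_barcode` (data.frame, or NULL).
#' @export
quality_stats <- function(reads, q = 20L) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$bins)) {
    per <- lapply(names(reads$bins), function(b) {
      s <- quality_stats(reads$bins[[b]], q)
      data.frame(barcode = b, n_reads = s$n_reads, called_nt = s$called_nt,
                 q20_nt = s$q20_nt, q20_pct = s$q20_pct,
                 stringsAsFactors = FALSE)
    })
    all_reads <- rbind(do.call(rbind, reads$bins), reads$unassigned)
    tot <- quality_stats(all_reads, q)
    tot$per_barcode <- do.call(rbind, per)
    return(tot)
  }
  scores <- phred_decode(reads$qualities)
  called <- sum(lengths(scores))
  q20 <- sum(vapply(scores, function(s) sum(s >= q), integer(1L)))
  list(n_reads = nrow(reads), called_nt = called, q20_nt = q20,
       q20_pct = if (called > 0) q20_percent(called, q20) else NA_real_,
       per_barcode = NULL)
}

#' Q20 percentage
#'
#' @param called_nt total called nucleotides (> 0).
#' @param q20_nt nucleotides at Phred >= 20.
#' @return `100 * q20_nt / called_nt`, rounded to 2 decimals.
#' @export
#' @examples
#' q20_percent(1000, 874)
q20_percent <- function(called_nt, q20_nt) {
  if (called_nt <= 0) stop("called_nt must be positive", call. = FALSE)
  if (q20_nt > called_nt || q20_nt < 0)
    stop("q20_nt must lie in [0, called_nt]", call. = FALSE)
  round(100 * q20_nt / called_nt, 2)
}

#' Minimum-length read filter
#'
#' Applied after primer trimming; reads of exactly `min_len` bases are
#' retained (the threshold is inclusive).
#'
#' @param reads read data.frame.
#' @param min_len minimum post-trim length.
#' @return list with `retained` (read data.frame) and `n_rejected`.
#' @export
length_filter <- function(reads, min_len = 40L) {
  keep <- nchar(reads$sequence) >= min_len
  retained <- reads[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, n_rejected = sum(!keep))
}

#' Sliding-window 3' quality trimming (optional)
#'
#' Scans windows from the 3' end and clips until the first window whose mean
#' Phred score reaches `min_mean_q`. Off by default in the pipeline: the
#' simulator emits already-polished reads, mirroring upstream base-calling
#' QC; provided for real data that skipped such a pass.
#'
#' @param reads read data.frame.
#' @param window window width in bases.
#' @param min_mean_q minimum window mean Phred score.
#' @return the read data.frame, 3' ends clipped.
#' @export
quality_trim <- function(reads, window = 10L, min_mean_q = 15) {
  if (!nrow(reads)) return(reads)
  for (i in seq_len(nrow(reads))) {
    s <- phred_decode(reads$qualities[i])[[1L]]
    end <- length(s)
    while (end >= window &&
           mean(s[(end - window + 1L):end]) < min_mean_q)
      end <- end - 1L
    if (end < window && length(s) >= window) end <- 0L
    if (end < length(s)) {
      reads$sequence[i] <- substr(reads$sequence[i], 1L, end)
      reads$qualities[i] <- substr(reads$qualities[i], 1L, end)
    }
  }
  reads
}
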