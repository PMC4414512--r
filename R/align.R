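#' Alignment scoring and filter thresholds
#'
#' Match/mismatch and affine gap parameters for the glocal aligner, plus the
#' downstream retention thresholds. An internal gap of length k costs
#' `gap_open + k * gap_extend`. Defaults mirror widely used short-read
#' aligner settings; the retention gates (read length >= 40 nt, mapping
#' quality >= 20) are the pipeline's filtering rule.
#'
#' @param match match reward (positive).
#' @param mismatch mismatch penalty (positive; subtracted).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param min_mapq minimum mapping quality retained, in `[0, 60]`.
#' @param min_len minimum read length retained.
#' @return an `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 1L, mismatch = 4L, gap_open = 6L,
                              gap_extend = 1L, min_mapq = 20L, min_len = 40L) {
  stopifnot(match > 0, mismatch > 0, gap_open > 0, gap_extend > 0,
            min_mapq >= 0, min_mapq <= 60)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_mapq = as.integer(min_mapq),
                 min_len = as.integer(min_len)),
            class = "alignment_scoring")
}

#' Glocal pairwise alignment of one read against one region
#'
#' Read-global, reference-local dynamic programming with affine gaps:
#' the read aligns end to end, reference bases outside the aligned window are
#' free. Traceback is deterministic with tie order diagonal > up (insertion)
#' > left (deletion); ties in the end column resolve to the fewest reference
#' bases.
#'
#' @param read read sequence (consumed fully).
#' @param region_seq reference target sequence.
#' @param scoring an [alignment_scoring()].
#' @return list with `score`, `cigar` (M/I/D, read-relative), `n_mismatch`,
#'   `n_ins`, `n_del`, `ref_start` (0-based) and `aligned_ref_bases`.
#' @export
#' @examples
#' glocal_align("ACGT", "TTACGTTT")
glocal_align <- function(read, region_seq, scoring = alignment_scoring()) {
  stopifnot(nzchar(read), nzchar(region_seq))
  .glocal_traceback(toupper(read), toupper(region_seq), scoring$match,
                    scoring$mismatch, scoring$gap_open, scoring$gap_extend)
}

#' Map reads against a reference panel
#'
#' Aligns every read (and its reverse complement) glocally against every
#' panel region, keeps the best-scoring (region, strand) candidate, and
#' scores its uniqueness as `mapq = min(60, 6 * (score - second_best))`,
#' where `second_best` ranges over all other (region, strand) candidates.
#' Exact ties get mapq 0 and are meant to be filtered, never randomly
#' assigned. Reads whose best score is not positive are reported unmapped.
#' `second_best` is reported exactly whenever it lies within 10 score units
#' of the best (the range where it affects the MAPQ) and as NA when every
#' other candidate is further away, i.e. MAPQ 60.
#'
#' @param reads data.frame with `read_id`, `sequence` (and optionally
#'   `qualities`), e.g. from [read_fastq()] or [trim_reads()].
#' @param panel an `amplicon_panel`.
#' @param scoring an [alignment_scoring()].
#' @return data.frame (one row per read): `read_id`, `species`, `pair`,
#'   `strand`, `score`, `second_best`, `mapq`, `n_mismatch`, `n_ins`,
#'   `n_del`, `aligned_ref_bases`, `cigar`, `ref_start`, `read_len`,
#'   `mapped`.
#' @export
map_reads <- function(reads, panel, scoring = alignment_scoring()) {
  stopifnot(inherits(panel, "amplicon_panel"), nrow(panel) >= 1L)
  if (!nrow(reads)) return(empty_alignments())
  seqs <- toupper(reads$sequence)
  refs <- toupper(panel$target_seq)
  # candidates further than 60/6 = 10 score units below the best cannot
  # change the MAPQ (it saturates at 60); the mapper prunes them and
  # reports second_best = NA for such reads
  hits <- .glocal_map(seqs, revcomp(seqs), refs, scoring$match,
                      scoring$mismatch, scoring$gap_open,
                      scoring$gap_extend, prune_margin = 10L)
  n_reg <- nrow(panel)
  strand <- ifelse(hits$best_idx > n_reg, "-", "+")
  reg_i <- ifelse(hits$best_idx > n_reg, hits$best_idx - n_reg,
                  hits$best_idx)
  mapq <- ifelse(is.na(hits$second_best), 60L,
                 as.integer(pmin(60, pmax(0, 6L * (hits$score - hits$second_best)))))
  data.frame(
    read_id = reads$read_id, species = panel$species[reg_i],
    pair = panel$pair[reg_i], strand = strand,
    score = hits$score, second_best = hits$second_best,
    mapq = mapq, n_mismatch = hits$n_mismatch, n_ins = hits$n_ins,
    n_del = hits$n_del, aligned_ref_bases = hits$aligned_ref_bases,
    cigar = hits$cigar, ref_start = hits$ref_start,
    read_len = nchar(seqs), mapped = hits$score > 0L,
    stringsAsFactors = FALSE)
}

#' @rdname map_reads
#' @param read single read sequence.
#' @export
map_read <- function(read, panel, scoring = alignment_scoring()) {
  map_reads(data.frame(read_id = "read1", sequence = read,
                       stringsAsFactors = FALSE), panel, scoring)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), species = character(0),
             pair = character(0), strand = character(0), score = integer(0),
             second_best = integer(0), mapq = integer(0),
             n_mismatch = integer(0), n_ins = integer(0), n_del = integer(0),
             aligned_ref_bases = integer(0), cigar = character(0),
             ref_start = integer(0), read_len = integer(0),
             mapped = logical(0), stringsAsFactors = FALSE)
}

#' Apply the retention filters to mapped reads
#'
#' Retains alignments with read length >= `min_len` and mapping quality >=
#' `min_mapq` (both thresholds inclusive); unmapped reads are always
#' rejected. The tally reports one count per rejection reason.
#'
#' @param results data.frame from [map_reads()].
#' @param scoring an [alignment_scoring()] carrying the thresholds.
#' @return list with `retained` (data.frame) and `rejected` (named integer
#'   vector: `unmapped`, `short_read`, `low_mapq`).
#' @export
filter_alignments <- function(results, scoring = alignment_scoring()) {
  unmapped <- !results$mapped
  short <- !unmapped & results$read_len < scoring$min_len
  lowq <- !unmapped & !short & results$mapq < scoring$min_mapq
  keep <- !(unmapped | short | lowq)
  list(retained = results[keep, , drop = FALSE],
       rejected = c(unmapped = sum(unmapped), short_read = sum(short),
                    low_mapq = sum(lowq)))
}

#' Write alignments as SAM
#'
#' Emits a valid SAM 1.x file: one `@SQ` line per panel region
#' (`SN = species|pair`, `LN` = region length), flag 16 for reverse-strand
#' alignments (sequence and qualities stored reverse-complemented, as SAM
#' requires), flag 4 for unmapped reads, and `NM` = mismatches + inserted +
#' deleted bases.
#'
#' @param results data.frame from [map_reads()].
#' @param reads the read data.frame that was mapped (for sequences and
#'   qualities).
#' @param panel the `amplicon_panel` mapped against.
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
write_sam <- function(results, reads, panel, path) {
  key <- panel_key(panel)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", key, nchar(panel$target_seq)),
           "@PG\tID:ampliconid\tPN:ampliconid")
  m <- match(results$read_id, reads$read_id)
  seqs <- toupper(reads$sequence[m])
  quals <- if ("qualities" %in% names(reads)) reads$qualities[m]
           else strrep("I", nchar(seqs))
  rev <- results$strand == "-" & results$mapped
  seqs[rev] <- revcomp(seqs[rev])
  quals[rev] <- vapply(strsplit(quals[rev], "", fixed = TRUE),
                       function(z) paste(rev(z), collapse = ""), character(1L))
  flag <- ifelse(!results$mapped, 4L, ifelse(rev, 16L, 0L))
  rname <- ifelse(results$mapped,
                  paste(results$species, results$pair, sep = "|"), "*")
  pos <- ifelse(results$mapped, results$ref_start + 1L, 0L)
  mapq <- ifelse(results$mapped, results$mapq, 0L)
  cig <- ifelse(results$mapped, results$cigar, "*")
  nm <- results$n_mismatch + results$n_ins + results$n_del
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                   results$read_id, flag, rname, pos, mapq, cig, seqs, quals,
                   ifelse(results$mapped, sprintf("\tNM:i:%d", nm), ""))
  con <- file(path, "w")
  on.exit(close(con))
  tryCatch(writeLines(c(hdr, lines), con),
           error = function(e) stop("failed writing SAM to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a per-read assignment table back from SAM
#'
#' Re-parses a SAM file written by [write_sam()] (via samtools-backed BAM
#' conversion) into the assignment fields used downstream.
#'
#' @param path SAM file.
#' @return data.frame with `read_id`, `species`, `pair`, `strand`, `mapq`,
#'   `cigar`, `ref_start`, `nm`, `mapped`.
#' @export
read_alignments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "mapq", "cigar", "flag"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  rn <- as.character(x$rname)
  tok <- strsplit(rn, "|", fixed = TRUE)
  mapped <- !bitwAnd(x$flag, 4L)
  data.frame(
    read_id = x$qname,
    species = ifelse(mapped, vapply(tok, function(z) z[1L], character(1L)), NA),
    pair = ifelse(mapped, vapply(tok, function(z) z[2L], character(1L)), NA),
    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
    mapq = x$mapq, cigar = x$cigar, ref_start = x$pos - 1L,
    nm = if (is.null(x$tag$NM)) NA_integer_ else x$tag$NM,
    mapped = mapped, stringsAsFactors = FALSE)
}
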