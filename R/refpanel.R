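#' Locate primer binding sites on a reference sequence
#'
#' Scans every window of the reference top strand for IUPAC-aware matches to
#' a primer within a mismatch tolerance. Ambiguity codes in the primer match
#' any compatible base at zero cost. For `orientation = "reverse"` the primer
#' (given 5'->3' as synthesized) is reverse-complemented before scanning, so
#' reported coordinates always refer to the top strand.
#'
#' @param reference DNA string to scan.
#' @param primer primer sequence 5'->3' (IUPAC codes allowed).
#' @param orientation `"forward"` or `"reverse"`.
#' @param max_mismatch maximum number of mismatching positions.
#' @param primer_name label copied into the result.
#' @return data.frame with columns `primer_name`, `orientation`, `start`,
#'   `end` (0-based half-open, top strand) and `mismatches`, sorted by
#'   (mismatches, start).
#' @export
#' @examples
#' find_primer_sites("TTTACGTACGTTTT", "ACGTACGT", "forward", 1)
find_primer_sites <- function(reference, primer,
                              orientation = c("forward", "reverse"),
                              max_mismatch = 3L, primer_name = NA_character_) {
  orientation <- match.arg(orientation)
  reference <- check_dna(reference, "reference")
  primer <- check_dna(primer, "primer")
  stopifnot(max_mismatch >= 0L, nchar(reference) >= nchar(primer))
  query <- if (orientation == "reverse") revcomp(primer) else primer
  subject <- Biostrings::DNAString(reference)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(query), subject,
                                   max.mismatch = max_mismatch, fixed = FALSE)
  starts <- Biostrings::start(hits)
  if (length(starts)) {
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(query), subject,
                                      starting.at = starts,
                                      with.indels = FALSE, fixed = FALSE)
  } else mm <- integer(0)
  out <- data.frame(primer_name = rep(primer_name, length(starts)),
                    orientation = rep(orientation, length(starts)),
                    start = starts - 1L,
                    end = starts - 1L + nchar(query),
                    mismatches = as.integer(mm),
                    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' In-silico PCR: predict the amplicon of a primer pair on one reference
#'
#' Finds forward and reverse primer sites on both strands of the reference
#' and pairs each forward site with downstream reverse sites within the
#' product-size cap. Among all candidate products the one with the fewest
#' total primer mismatches wins; ties break to the shortest product, then to
#' the leftmost site on the plus strand. The returned target region excludes
#' both primers.
#'
#' @param reference DNA string (a linearized mitochondrial sequence, say).
#' @param pair a [primer_pair()].
#' @param max_mismatch per-primer mismatch tolerance (default 3; universal
#'   primers are expected to carry a few mismatches on distant taxa).
#' @param max_product maximum full product length considered.
#' @param species,source_id labels carried into the region.
#' @return an `amplicon_region`: list with fields `species`, `pair`,
#'   `target_seq`, `source_id`, `target_start`, `target_end` (0-based
#'   half-open on the scanned strand), `strand` (`"+"` if found on the stored
#'   orientation), `full_len`, `mm_fwd`, `mm_rev`.
#' @export
in_silico_pcr <- function(reference, pair, max_mismatch = 3L,
                          max_product = 1000L, species = NA_character_,
                          source_id = NA_character_) {
  stopifnot(inherits(pair, "primer_pair"))
  reference <- check_dna(reference, "reference")
  plen <- nchar(pair$forward) + nchar(pair$reverse)
  if (max_product <= plen)
    stop("max_product must exceed the summed primer lengths", call. = FALSE)
  best <- NULL
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") reference else revcomp(reference)
    if (nchar(seq_s) < max(nchar(pair$forward), nchar(pair$reverse))) next
    fw <- find_primer_sites(seq_s, pair$forward, "forward", max_mismatch)
    rv <- find_primer_sites(seq_s, pair$reverse, "reverse", max_mismatch)
    if (!nrow(fw) || !nrow(rv)) next
    for (i in seq_len(nrow(fw))) for (j in seq_len(nrow(rv))) {
      if (rv$start[j] < fw$end[i]) next
      prod_len <- rv$end[j] - fw$start[i]
      if (prod_len > max_product) next
      cand <- list(strand = strand, f = fw[i, ], r = rv[j, ],
                   mm = fw$mismatches[i] + rv$mismatches[j],
                   prod_len = prod_len, seq_s = seq_s)
      if (is.null(best) || cand$mm < best$mm ||
          (cand$mm == best$mm && cand$prod_len < best$prod_len) ||
          (cand$mm == best$mm && cand$prod_len == best$prod_len &&
           best$strand == "-" && cand$strand == "+"))
        best <- cand
    }
  }
  if (is.null(best))
    stop("no amplicon for pair ", pair$name, " on reference ",
         if (is.na(source_id)) "(unnamed)" else source_id, call. = FALSE)
  t0 <- best$f$end
  t1 <- best$r$start
  structure(list(
    species = species, pair = pair$name,
    target_seq = substr(best$seq_s, t0 + 1L, t1),
    source_id = source_id, target_start = t0, target_end = t1,
    strand = best$strand, full_len = best$prod_len,
    mm_fwd = best$f$mismatches, mm_rev = best$r$mismatches),
    class = "amplicon_region")
}

#' @export
print.amplicon_region <- function(x, ...) {
  cat(sprintf("Amplicon region %s|%s|%s|%d-%d (%s): target %d bp, full %d bp, mm %d+%d\n",
              x$species, x$pair, x$source_id, x$target_start, x$target_end,
              x$strand, nchar(x$target_seq), x$full_len, x$mm_fwd, x$mm_rev))
  invisible(x)
}

#' Read reference sequences with species labels from FASTA
#'
#' The species label is taken from a `species=` key in the record description
#' or, failing that, from a sidecar map of sequence id to species.
#'
#' @param path FASTA file.
#' @param species_map optional named character vector (id -> species) or a
#'   two-column TSV path (`id`, `species`).
#' @return data.frame with columns `source_id`, `species`, `sequence`.
#' @export
read_reference_fasta <- function(path, species_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  full <- names(seqs)
  id <- sub("\\s.*$", "", full)
  sp <- rep(NA_character_, length(full))
  hit <- regmatches(full, regexpr("species=[^ \t]+", full))
  has <- grepl("species=", full, fixed = TRUE)
  sp[has] <- sub("^species=", "", hit)
  if (is.character(species_map) && length(species_map) == 1L &&
      file.exists(species_map)) {
    m <- read.delim(species_map, stringsAsFactors = FALSE)
    species_map <- setNames(m$species, m$id)
  }
  if (!is.null(species_map)) {
    miss <- is.na(sp) & id %in% names(species_map)
    sp[miss] <- species_map[id[miss]]
  }
  if (anyNA(sp))
    stop("no species label for record(s): ",
         paste(head(id[is.na(sp)], 3L), collapse = ", "), call. = FALSE)
  data.frame(source_id = id, species = sp,
             sequence = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build a multi-species amplicon reference panel
#'
#' Runs [in_silico_pcr()] for every (reference, primer pair) combination and
#' collects the resulting target regions. Missing combinations (no compatible
#' site pair within tolerance) are reported as warnings, not errors, since
#' some universal pairs genuinely fail on some taxa.
#'
#' @param references a data.frame as returned by [read_reference_fasta()], or
#'   a named character vector of sequences (names = species).
#' @param pairs a [primer_set()].
#' @param max_mismatch per-primer mismatch tolerance.
#' @param max_product maximum product length considered.
#' @param keep_first if several references yield the same (species, pair),
#'   keep the first instead of erroring.
#' @return an `amplicon_panel`: data.frame keyed by (species, pair) with the
#'   region coordinates, mismatch counts and target sequences; the primer set
#'   is attached as attribute `"pairs"`.
#' @export
build_panel <- function(references, pairs, max_mismatch = 3L,
                        max_product = 1000L, keep_first = FALSE) {
  stopifnot(inherits(pairs, "primer_set"))
  if (is.character(references))
    references <- data.frame(source_id = names(references),
                             species = names(references),
                             sequence = unname(references),
                             stringsAsFactors = FALSE)
  rows <- list()
  missing <- character(0)
  for (i in seq_len(nrow(references))) for (p in pairs) {
    reg <- tryCatch(
      in_silico_pcr(references$sequence[i], p, max_mismatch, max_product,
                    species = references$species[i],
                    source_id = references$source_id[i]),
      error = function(e) NULL)
    if (is.null(reg)) {
      missing <- c(missing, paste0(references$species[i], "/", p$name))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      species = reg$species, pair = reg$pair, source_id = reg$source_id,
      target_start = reg$target_start, target_end = reg$target_end,
      strand = reg$strand, full_len = reg$full_len,
      mm_fwd = reg$mm_fwd, mm_rev = reg$mm_rev,
      target_seq = reg$target_seq, provenance = "in_silico_pcr",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no amplicon found for any (reference, pair) combination",
         call. = FALSE)
  panel <- do.call(rbind, rows)
  key <- paste(panel$species, panel$pair, sep = "|")
  if (anyDuplicated(key)) {
    if (!keep_first)
      stop("duplicate (species, pair) combinations: ",
           paste(unique(key[duplicated(key)]), collapse = ", "),
           "; pass keep_first = TRUE to keep the first record", call. = FALSE)
    panel <- panel[!duplicated(key), , drop = FALSE]
  }
  if (length(missing))
    warning("no amplicon for: ", paste(missing, collapse = ", "),
            call. = FALSE)
  rownames(panel) <- NULL
  structure(panel, pairs = pairs, class = c("amplicon_panel", "data.frame"))
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("Amplicon reference panel:", nrow(x), "regions,",
      length(unique(x$species)), "species,",
      length(unique(x$pair)), "primer pairs\n")
  print.data.frame(x[, setdiff(names(x), "target_seq")], ...)
  invisible(x)
}

panel_key <- function(panel) paste(panel$species, panel$pair, sep = "|")

#' Extract the target interval from its source reference
#'
#' Applies a panel row's coordinates back to the reference it was built from;
#' used to check coordinate bookkeeping.
#' @param region one-row panel slice or `amplicon_region`.
#' @param reference the source sequence (stored orientation).
#' @return the extracted target sequence.
#' @export
extract_region <- function(region, reference) {
  seq_s <- if (region$strand == "+") toupper(reference) else revcomp(reference)
  substr(seq_s, region$target_start + 1L, region$target_end)
}

#' Serialize / load an amplicon panel as FASTA
#'
#' Headers follow `species|pair|source_id|start-end` (0-based half-open) with
#' auxiliary `key=value` fields in the description, so a panel round-trips
#' identically.
#'
#' @param panel an `amplicon_panel`.
#' @param path FASTA path.
#' @param pairs primer set to attach on load (defaults to
#'   [meat_primer_pairs()] when the stored names all match).
#' @return `write_panel()` the path, invisibly; `read_panel()` the panel.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "amplicon_panel"))
  hdr <- sprintf("%s|%s|%s|%d-%d strand=%s full_len=%d mm=%d,%d provenance=%s",
                 panel$species, panel$pair, panel$source_id,
                 panel$target_start, panel$target_end, panel$strand,
                 panel$full_len, panel$mm_fwd, panel$mm_rev,
                 panel$provenance)
  x <- Biostrings::DNAStringSet(panel$target_seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, pairs = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  tok <- strsplit(sub("\\s.*$", "", full), "|", fixed = TRUE)
  if (any(lengths(tok) != 4L))
    stop("panel FASTA headers must be species|pair|source_id|start-end",
         call. = FALSE)
  coords <- strsplit(vapply(tok, `[[`, character(1L), 4L), "-", fixed = TRUE)
  get_field <- function(key, default) {
    hit <- regmatches(full, regexpr(paste0(key, "=[^ \t]+"), full))
    out <- rep(default, length(full))
    out[grepl(paste0(key, "="), full)] <- sub(paste0("^", key, "="), "", hit)
    out
  }
  panel <- data.frame(
    species = vapply(tok, `[[`, character(1L), 1L),
    pair = vapply(tok, `[[`, character(1L), 2L),
    source_id = vapply(tok, `[[`, character(1L), 3L),
    target_start = as.integer(vapply(coords, `[[`, character(1L), 1L)),
    target_end = as.integer(vapply(coords, `[[`, character(1L), 2L)),
    strand = get_field("strand", "+"),
    full_len = as.integer(get_field("full_len", NA_character_)),
    mm_fwd = NA_integer_,
    mm_rev = NA_integer_,
    target_seq = as.character(x),
    provenance = get_field("provenance", "unknown"),
    stringsAsFactors = FALSE, row.names = NULL)
  mmf <- get_field("mm", NA_character_)
  mm2 <- strsplit(mmf, ",", fixed = TRUE)
  panel$mm_fwd <- as.integer(vapply(mm2, function(z) z[1L], character(1L)))
  panel$mm_rev <- as.integer(vapply(mm2, function(z) if (length(z) > 1L) z[2L] else NA_character_, character(1L)))
  if (is.null(pairs)) {
    std <- meat_primer_pairs()
    if (all(panel$pair %in% names(std))) pairs <- std
  }
  structure(panel, pairs = pairs, class = c("amplicon_panel", "data.frame"))
}

#' Write the panel manifest TSV
#'
#' One row per region: species, pair, source_id, start, end, strand,
#' full_len, mismatches_fwd, mismatches_rev.
#' @param panel an `amplicon_panel`.
#' @param path output TSV.
#' @export
write_panel_manifest <- function(panel, path) {
  df <- data.frame(species = panel$species, pair = panel$pair,
                   source_id = panel$source_id, start = panel$target_start,
                   end = panel$target_end, strand = panel$strand,
                   full_len = panel$full_len,
                   mismatches_fwd = panel$mm_fwd,
                   mismatches_rev = panel$mm_rev, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inter-species discriminability of one target region
#'
#' Computes the pairwise p-distance (mismatches plus gap columns over aligned
#' columns, from glocal pairwise alignment) between the target sequences of
#' every species for one primer pair. A positive minimum inter-species
#' distance is the precondition for unambiguous read assignment.
#'
#' @param panel an `amplicon_panel`.
#' @param pair_name primer pair to report on.
#' @param scoring an [alignment_scoring()].
#' @return list with `distances` (symmetric matrix, zero diagonal),
#'   `min_distance`, and `pair`.
#' @export
discriminability_report <- function(panel, pair_name,
                                    scoring = alignment_scoring()) {
  sub <- panel[panel$pair == pair_name, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("discriminability needs at least 2 species for pair ", pair_name,
         call. = FALSE)
  sp <- sub$species
  d <- matrix(0, nrow(sub), nrow(sub), dimnames = list(sp, sp))
  for (i in seq_len(nrow(sub) - 1L)) for (j in (i + 1L):nrow(sub)) {
    a <- sub$target_seq[i]; b <- sub$target_seq[j]
    # align the shorter onto the longer so the read-global constraint
    # penalizes length differences as gap columns symmetrically
    if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
      tmp <- a; a <- b; b <- tmp
    }
    al <- glocal_align(a, b, scoring)
    cols <- nchar(a) + al$n_del
    d[i, j] <- d[j, i] <- (al$n_mismatch + al$n_ins + al$n_del) / cols
  }
  list(distances = d, min_distance = min(d[upper.tri(d)]), pair = pair_name)
}
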