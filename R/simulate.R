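#' Per-(species, pair) amplification efficiency model
#'
#' Multiplicative weights modifying how strongly each (species, primer pair)
#' combination amplifies relative to its DNA mass. A weight of 0 encodes
#' amplification failure (e.g. PCR competition suppressing avian templates
#' for one pair in mixed pools). Weights default to 1; they can be set
#' explicitly or derived from primer-site mismatches recorded in a panel as
#' `mismatch_decay ^ (mm_fwd + mm_rev)`.
#'
#' @param weights named numeric vector keyed `"species|pair"`, or NULL.
#' @param mismatch_decay per-mismatch multiplicative factor in `(0, 1]` used
#'   by [efficiency_from_panel()]; stored as metadata here.
#' @return an `efficiency_model`.
#' @export
#' @examples
#' eff <- set_efficiency(efficiency_model(), "chicken", "16S_Ki", 0)
efficiency_model <- function(weights = NULL, mismatch_decay = NULL) {
  if (!is.null(weights)) {
    if (!is.numeric(weights) || is.null(names(weights)))
      stop("weights must be a named numeric vector keyed species|pair",
           call. = FALSE)
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("efficiency weights must be finite and >= 0", call. = FALSE)
  }
  structure(list(weights = weights, mismatch_decay = mismatch_decay),
            class = "efficiency_model")
}

#' @rdname efficiency_model
#' @param eff an `efficiency_model`.
#' @param species,pair the combination to set.
#' @param weight new weight (finite, >= 0).
#' @export
set_efficiency <- function(eff, species, pair, weight) {
  stopifnot(inherits(eff, "efficiency_model"), is.finite(weight), weight >= 0)
  w <- eff$weights %||% setNames(numeric(0), character(0))
  for (k in paste(species, pair, sep = "|")) w[k] <- weight
  efficiency_model(w, eff$mismatch_decay)
}

#' @rdname efficiency_model
#' @param panel an `amplicon_panel` with recorded primer-site mismatches.
#' @export
efficiency_from_panel <- function(panel, mismatch_decay = 0.5) {
  stopifnot(inherits(panel, "amplicon_panel"),
            mismatch_decay > 0, mismatch_decay <= 1)
  w <- setNames(mismatch_decay ^ (panel$mm_fwd + panel$mm_rev),
                panel_key(panel))
  efficiency_model(w, mismatch_decay)
}

efficiency_weight <- function(eff, species, pair) {
  k <- paste(species, pair, sep = "|")
  out <- rep(1, length(k))
  if (!is.null(eff$weights)) {
    hit <- k %in% names(eff$weights)
    out[hit] <- unname(eff$weights[k[hit]])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected read allocation over (species, primer pair)
#'
#' Each primer pair's amplicon contributes an equal volume to the library
#' (the amplicons are mixed at equal PCR volume), so probabilities are
#' normalized within each pair: P(species | pair) is proportional to the
#' species' per-reaction DNA mass times its amplification efficiency.
#'
#' @param pool a [pool_spec()].
#' @param panel an `amplicon_panel` (species missing a region for some pair
#'   simply cannot emit reads for that pair).
#' @param eff an [efficiency_model()].
#' @return data.frame with `species`, `pair`, `prob`; `prob` sums to 1
#'   within each pair.
#' @export
expected_read_weights <- function(pool, panel, eff = efficiency_model()) {
  stopifnot(inherits(pool, "pool_spec"), inherits(panel, "amplicon_panel"))
  absent <- setdiff(names(pool$masses), unique(panel$species))
  if (length(absent))
    stop("pool species missing from the panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  ng <- per_reaction_ng(pool)
  out <- list()
  for (p in unique(panel$pair)) {
    sp <- intersect(names(pool$masses),
                    panel$species[panel$pair == p])
    if (!length(sp)) next
    w <- ng[sp] * efficiency_weight(eff, sp, p)
    if (sum(w) == 0)
      stop("all amplification weights are zero for pair ", p, call. = FALSE)
    out[[p]] <- data.frame(species = sp, pair = p, prob = unname(w / sum(w)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sequencing error model for semiconductor amplicon reads
#'
#' Two error classes: uniform per-base substitutions, and homopolymer length
#' errors - each maximal run of an identical base of length L >= 2 gains or
#' loses one base with probability `hp_indel_rate(L)`, the characteristic
#' failure mode of flow-based base calling (run length must be inferred from
#' signal intensity, so long runs are called less accurately). The rate
#' function must be non-decreasing in L.
#'
#' @param sub_rate per-base substitution probability.
#' @param hp_indel_rate function of run length L returning the +-1 length
#'   error probability; defaults to `min(hp_slope * (L - 1), hp_cap)`.
#' @param hp_slope,hp_cap parameters of the default rate function; defaults
#'   calibrated so simulated per-base error rates land inside the
#'   0.0003-0.0181 band observed on real amplicon runs.
#' @param read_qual constant Phred score assigned to simulated bases.
#' @return an `error_model`.
#' @export
error_model <- function(sub_rate = 0.002, hp_indel_rate = NULL,
                        hp_slope = 0.01, hp_cap = 0.2, read_qual = 28L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, read_qual >= 2, read_qual <= 41)
  if (is.null(hp_indel_rate))
    hp_indel_rate <- function(L) pmin(hp_slope * pmax(L - 1, 0), hp_cap)
  r <- hp_indel_rate(1:25)
  if (any(r < 0) || any(r > 1) || is.unsorted(r))
    stop("hp_indel_rate must be non-decreasing with values in [0, 1]",
         call. = FALSE)
  structure(list(sub_rate = sub_rate, hp_indel_rate = hp_indel_rate,
                 read_qual = as.integer(read_qual)),
            class = "error_model")
}

#' Apply the error model to one sequence
#'
#' Substitutions are drawn per base (uniform over the three alternatives)
#' first; then each maximal homopolymer run of length >= 2 in the
#' substituted sequence suffers a +1/-1 length change with probability
#' `hp_indel_rate(L)`, direction equiprobable. Uses the current RNG state.
#'
#' @param sequence DNA string.
#' @param err an [error_model()].
#' @return list with `sequence` (mutated), `script` (data.frame `type`,
#'   `pos`, `ref`, `alt`; substitution positions are on the input sequence,
#'   indel positions are run starts after substitution), and the counts
#'   `n_sub`, `n_ins`, `n_del`.
#' @export
apply_error_model <- function(sequence, err = error_model()) {
  stopifnot(nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  ev_type <- character(0); ev_pos <- integer(0)
  ev_ref <- character(0); ev_alt <- character(0)
  sub_i <- which(runif(L) < err$sub_rate)
  for (i in sub_i) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    ev_type <- c(ev_type, "sub"); ev_pos <- c(ev_pos, i)
    ev_ref <- c(ev_ref, chars[i]); ev_alt <- c(ev_alt, alt)
    chars[i] <- alt
  }
  r <- rle(chars)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  delta <- integer(length(r$lengths))
  cand <- which(r$lengths >= 2L)
  if (length(cand)) {
    hit <- cand[runif(length(cand)) < err$hp_indel_rate(r$lengths[cand])]
    for (k in hit) {
      d <- sample(c(-1L, 1L), 1L)
      delta[k] <- d
      ev_type <- c(ev_type, if (d > 0L) "ins" else "del")
      ev_pos <- c(ev_pos, starts[k])
      ev_ref <- c(ev_ref, r$values[k])
      ev_alt <- c(ev_alt, r$values[k])
    }
  }
  if (any(delta != 0L)) {
    newseq <- paste(rep.int(r$values, r$lengths + delta), collapse = "")
  } else newseq <- paste(chars, collapse = "")
  list(sequence = newseq,
       script = data.frame(type = ev_type, pos = ev_pos, ref = ev_ref,
                           alt = ev_alt, stringsAsFactors = FALSE),
       n_sub = length(sub_i), n_ins = sum(delta > 0L),
       n_del = sum(delta < 0L))
}

#' Simulate a sequencing library from a DNA pool
#'
#' Draws read origins multinomially from [expected_read_weights()] (pairs
#' contribute equal volumes), picks a strand uniformly, applies the error
#' model to the target region, and assembles each read as
#' `forward primer + mutated target + revcomp(reverse primer)` (reverse
#' complemented as a whole for minus-strand reads). Primer bases are emitted
#' error-free so the truth table stays exactly recoverable by re-aligning the
#' trimmed read to its source region. Identical seeds give identical output.
#'
#' @param pool a [pool_spec()].
#' @param panel an `amplicon_panel` with its primer set attached.
#' @param eff an [efficiency_model()].
#' @param err an [error_model()].
#' @param n_reads number of reads to draw.
#' @param seed integer seed (mandatory: libraries are reproducible fixtures).
#' @param barcode optional barcode sequence prepended to every read (5').
#' @param read_id_prefix prefix for generated read ids.
#' @return list with `reads` (data.frame `read_id`, `sequence`,
#'   `qualities`) and `truth` (data.frame `read_id`, `species`, `pair`,
#'   `strand`, `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_library <- function(pool, panel, eff = efficiency_model(),
                             err = error_model(), n_reads, seed,
                             barcode = NULL, read_id_prefix = "sim") {
  stopifnot(n_reads > 0, !missing(seed))
  pairs <- attr(panel, "pairs")
  if (is.null(pairs))
    stop("panel carries no primer set; build it with build_panel() or ",
         "attach one via read_panel(pairs = ...)", call. = FALSE)
  w <- expected_read_weights(pool, panel, eff)
  n_pairs <- length(unique(w$pair))
  joint <- w$prob / n_pairs
  pkey <- panel_key(panel)
  reg_i <- match(paste(w$species, w$pair, sep = "|"), pkey)
  fw <- vapply(pairs, `[[`, character(1L), "forward")
  rv_rc <- setNames(revcomp(vapply(pairs, `[[`, character(1L), "reverse")),
                    names(pairs))
  with_seed(seed, {
    cell <- sample.int(nrow(w), n_reads, replace = TRUE, prob = joint)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    n_sub <- integer(n_reads); n_ins <- integer(n_reads)
    n_del <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      k <- cell[i]
      mut <- apply_error_model(panel$target_seq[reg_i[k]], err)
      seqs[i] <- paste0(fw[w$pair[k]], mut$sequence, rv_rc[w$pair[k]])
      n_sub[i] <- mut$n_sub; n_ins[i] <- mut$n_ins; n_del[i] <- mut$n_del
    }
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    # the barcode sits at the 5' end of the read as sequenced, whichever
    # strand of the amplicon was read
    if (!is.null(barcode))
      seqs <- paste0(check_dna(barcode, "barcode"), seqs)
    ids <- sprintf("%s_%06d", read_id_prefix, seq_len(n_reads))
    quals <- strrep(intToUtf8(err$read_qual + 33L), nchar(seqs))
    list(reads = data.frame(read_id = ids, sequence = seqs,
                            qualities = quals, stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, species = w$species[cell],
                            pair = w$pair[cell], strand = strand,
                            n_sub = n_sub, n_ins = n_ins, n_del = n_del,
                            stringsAsFactors = FALSE))
  })
}

#' Read / write a simulation truth table as TSV
#' @param truth the truth data.frame from [simulate_library()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read.delim(path, stringsAsFactors = FALSE)
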