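#' Per-region read counting
#'
#' Turns filtered alignments into the pipeline's central quantitative
#' object: mapped-read counts per (species, primer pair). Panel combinations
#' with no reads are reported as explicit zeros so downstream comparisons
#' share a key set.
#'
#' @param filtered data.frame of retained alignments (from
#'   [filter_alignments()]`$retained`), or any data.frame with `species` and
#'   `pair` columns, one row per retained read.
#' @param library_id label for the counted library.
#' @param panel optional `amplicon_panel` (or data.frame with `species`,
#'   `pair`) fixing the full key set.
#' @param unassigned number of input reads that were filtered out or
#'   unmapped, carried for read-conservation checks.
#' @return a `count_table`: data.frame `species`, `pair`, `count` with
#'   attributes `library_id` and `unassigned`.
#' @export
count_by_region <- function(filtered, library_id = "library",
                            panel = NULL, unassigned = 0L) {
  key_levels <- if (!is.null(panel))
    unique(paste(panel$species, panel$pair, sep = "|"))
  else unique(paste(filtered$species, filtered$pair, sep = "|"))
  key <- paste(filtered$species, filtered$pair, sep = "|")
  if (!all(key %in% key_levels))
    stop("alignments reference regions absent from the panel", call. = FALSE)
  tab <- table(factor(key, levels = key_levels))
  parts <- strsplit(key_levels, "|", fixed = TRUE)
  out <- data.frame(species = vapply(parts, `[[`, character(1L), 1L),
                    pair = vapply(parts, `[[`, character(1L), 2L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  count_table(out, library_id, unassigned)
}

#' @rdname count_by_region
#' @param counts data.frame with `species`, `pair`, `count`.
#' @export
count_table <- function(counts, library_id = "library", unassigned = 0L) {
  stopifnot(all(c("species", "pair", "count") %in% names(counts)),
            all(counts$count >= 0))
  if (anyDuplicated(paste(counts$species, counts$pair)))
    stop("duplicate (species, pair) cells in count table", call. = FALSE)
  rownames(counts) <- NULL
  structure(counts, library_id = library_id,
            unassigned = as.integer(unassigned),
            class = c("count_table", "data.frame"))
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table for", attr(x, "library_id"), "-",
      sum(x$count), "assigned reads,", attr(x, "unassigned"),
      "unassigned\n")
  wide <- tapply(x$count, list(x$species, x$pair), sum)
  wide[is.na(wide)] <- 0
  print(wide)
  invisible(x)
}

#' Column and row totals of a count table
#' @param table a `count_table`.
#' @return named integer vector of totals per primer pair (or per species).
#' @export
pair_totals <- function(table) {
  vapply(split(table$count, table$pair), sum, numeric(1L))
}

#' @rdname pair_totals
#' @export
species_totals <- function(table) {
  vapply(split(table$count, table$species), sum, numeric(1L))
}

#' Per-species totals and within-pair proportions
#'
#' @param table a `count_table`.
#' @param classes optional named species -> class map; adds per-class
#'   proportions within each pair.
#' @return list with `species_totals`, `proportions` (data.frame `species`,
#'   `pair`, `prop`; proportions sum to 1 within each pair with a nonzero
#'   total, NA for all-zero pairs) and, given `classes`, `class_proportions`.
#' @export
aggregate_by_species <- function(table, classes = NULL) {
  stopifnot(nrow(table) > 0L)
  tot <- pair_totals(table)
  prop <- table$count / ifelse(tot[table$pair] > 0, tot[table$pair], NA_real_)
  props <- data.frame(species = table$species, pair = table$pair,
                      prop = as.numeric(prop), stringsAsFactors = FALSE)
  out <- list(species_totals = species_totals(table), proportions = props)
  if (!is.null(classes)) {
    cls <- classes[table$species]
    agg <- tapply(table$count, list(cls, table$pair), sum)
    agg[is.na(agg)] <- 0
    out$class_proportions <- sweep(agg, 2L, colSums(agg), "/")
  }
  out
}

#' Reads per nanogram of per-reaction DNA
#'
#' Divides each count by the nanograms of that species' DNA present in one
#' PCR reaction (from the pool spec), a rough between-species comparison of
#' amplification efficiency.
#'
#' @param table a `count_table`.
#' @param pool a [pool_spec()] covering every counted species.
#' @return data.frame `species`, `pair`, `count`, `reaction_ng`,
#'   `reads_per_ng`.
#' @export
normalize_per_ng <- function(table, pool) {
  ng <- per_reaction_ng(pool)
  miss <- setdiff(unique(table$species), names(ng))
  if (length(miss))
    stop("species missing from pool spec: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.frame(species = table$species, pair = table$pair,
             count = table$count,
             reaction_ng = unname(ng[table$species]),
             reads_per_ng = table$count / unname(ng[table$species]),
             stringsAsFactors = FALSE)
}

#' Per-base error rates from filtered alignments
#'
#' For each (species, pair): errors divided by aligned reference bases.
#' By default the numerator counts substitutions plus inserted and deleted
#' bases, since homopolymer indels dominate semiconductor sequencing error;
#' `include_indels = FALSE` gives a substitutions-only rate for sensitivity
#' analysis. The denominator is reference bases (not read bases) so the rate
#' stays in `[0, 1]` under deletions. Cells with zero aligned bases are
#' omitted.
#'
#' @param filtered retained alignments carrying `n_mismatch`, `n_ins`,
#'   `n_del` and `aligned_ref_bases`.
#' @param include_indels count indel bases in the numerator.
#' @return an `error_rate_table`: data.frame `species`, `pair`,
#'   `mismatch_bases`, `inserted_bases`, `deleted_bases`,
#'   `aligned_ref_bases`, `rate`, plus marginal rates per pair and per
#'   species as attributes `pair_rates` and `species_rates`.
#' @export
estimate_error_rates <- function(filtered, include_indels = TRUE) {
  key <- interaction(filtered$species, filtered$pair, drop = TRUE, sep = "|")
  agg <- function(v) as.numeric(tapply(v, key, sum))
  parts <- strsplit(levels(key), "|", fixed = TRUE)
  out <- data.frame(
    species = vapply(parts, `[[`, character(1L), 1L),
    pair = vapply(parts, `[[`, character(1L), 2L),
    mismatch_bases = agg(filtered$n_mismatch),
    inserted_bases = agg(filtered$n_ins),
    deleted_bases = agg(filtered$n_del),
    aligned_ref_bases = agg(filtered$aligned_ref_bases),
    stringsAsFactors = FALSE)
  out <- out[out$aligned_ref_bases > 0, , drop = FALSE]
  num <- out$mismatch_bases +
    if (include_indels) out$inserted_bases + out$deleted_bases else 0
  out$rate <- num / out$aligned_ref_bases
  marg <- function(by) {
    n <- tapply(num, by, sum)
    d <- tapply(out$aligned_ref_bases, by, sum)
    setNames(as.numeric(n / d), names(n))
  }
  rownames(out) <- NULL
  structure(out, pair_rates = marg(out$pair),
            species_rates = marg(out$species),
            class = c("error_rate_table", "data.frame"))
}

#' Pearson correlation between two count vectors
#'
#' Standard product-moment correlation on raw counts, reported to 3
#' decimals; a constant (or too short) vector makes the correlation
#' undefined and returns NA with a warning rather than a spurious value.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return the correlation, rounded to 3 decimals (NA if undefined).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant vector", call. = FALSE)
    return(NA_real_)
  }
  round(cor(x, y, method = "pearson"), 3)
}

#' Species detection calls from a count table
#'
#' A species is called detected when at least `min_pairs` primer pairs each
#' carry at least `min_reads` assigned reads. No community-standard read
#' threshold exists for calling a minor component, so both knobs are
#' explicit and default conservatively low (`min_reads = 2`,
#' `min_pairs = 1`).
#'
#' @param table a `count_table`.
#' @param min_reads minimum reads per supporting pair (>= 1).
#' @param min_pairs minimum number of supporting pairs (>= 1).
#' @param species optional species universe (e.g. all panel species);
#'   species absent from the table are reported undetected.
#' @return data.frame `species`, `detected`, `n_supporting_pairs`,
#'   `supporting_pairs`, `total_reads`, `min_reads`, `min_pairs`.
#' @export
call_species <- function(table, min_reads = 2L, min_pairs = 1L,
                         species = NULL) {
  stopifnot(min_reads >= 1L, min_pairs >= 1L)
  sp <- species %||% unique(table$species)
  rows <- lapply(sp, function(s) {
    sub <- table[table$species == s & table$count >= min_reads, ,
                 drop = FALSE]
    data.frame(species = s, detected = nrow(sub) >= min_pairs,
               n_supporting_pairs = nrow(sub),
               supporting_pairs = paste(sub$pair, collapse = ","),
               total_reads = sum(table$count[table$species == s]),
               min_reads = min_reads, min_pairs = min_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation matrix between libraries over count-table slices
#'
#' Correlates two (or more) libraries' counts over shared (species, pair)
#' cells, sliced the way replicate runs are usually compared: all cells,
#' per species class, per primer pair, and pair-by-class. Slices in which
#' either library is constant (e.g. an all-zero avian column) are flagged
#' degenerate instead of reporting a meaningless coefficient.
#'
#' @param tables list of >= 2 `count_table` objects.
#' @param classes named species -> class map (default
#'   [meat_species_classes()]).
#' @return data.frame `library_a`, `library_b`, `slice`, `r`, `n`,
#'   `degenerate`.
#' @export
compare_libraries <- function(tables, classes = meat_species_classes()) {
  stopifnot(length(tables) >= 2L)
  ids <- vapply(tables, function(t) attr(t, "library_id"), character(1L))
  keys <- lapply(tables, function(t) paste(t$species, t$pair, sep = "|"))
  shared <- Reduce(intersect, keys)
  if (!length(shared))
    stop("libraries share no (species, pair) cells", call. = FALSE)
  base <- tables[[1L]][match(shared, keys[[1L]]), c("species", "pair")]
  slices <- c(list(all = rep(TRUE, length(shared))),
              lapply(split(seq_along(shared), classes[base$species]),
                     function(i) seq_along(shared) %in% i),
              lapply(split(seq_along(shared), base$pair),
                     function(i) seq_along(shared) %in% i))
  for (p in unique(base$pair)) for (cl in unique(classes[base$species])) {
    slices[[paste(p, cl, sep = "_")]] <-
      base$pair == p & classes[base$species] == cl
  }
  out <- list()
  for (a in seq_len(length(tables) - 1L)) for (b in (a + 1L):length(tables)) {
    xa <- tables[[a]]$count[match(shared, keys[[a]])]
    xb <- tables[[b]]$count[match(shared, keys[[b]])]
    for (s in names(slices)) {
      i <- slices[[s]]
      if (sum(i) < 3L) next
      degen <- stats::sd(xa[i]) == 0 || stats::sd(xb[i]) == 0
      out[[length(out) + 1L]] <- data.frame(
        library_a = ids[a], library_b = ids[b], slice = s,
        r = if (degen) NA_real_ else round(cor(xa[i], xb[i]), 3),
        n = sum(i), degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Published dilution-series read counts (libraries 4 and 5)
#'
#' Mapped-read counts per (species, primer pair) from the published
#' dilution-series sequencing experiment this toolkit models: seven
#' mammalian species, with pig and horse DNA at 1:10 (library 4) and 1:50
#' (library 5) of the other species. Bundled as reference data for
#' threshold and correlation arithmetic.
#'
#' @return list with `lib4` and `lib5` (`count_table` objects) and `data`
#'   (the raw data.frame).
#' @export
#' @examples
#' pair_totals(dilution_series_counts()$lib4)
dilution_series_counts <- function() {
  path <- system.file("extdata", "dilution_series_counts.tsv",
                      package = "ampliconid", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  mk <- function(col, id) count_table(
    data.frame(species = df$species, pair = df$pair, count = df[[col]],
               stringsAsFactors = FALSE), library_id = id)
  list(lib4 = mk("lib4_1to10", "library4_1to10"),
       lib5 = mk("lib5_1to50", "library5_1to50"),
       data = df)
}

#' Write a count, error-rate or comparison table as TSV
#' @param x a data.frame-backed result object.
#' @param path output TSV path.
#' @export
write_tsv_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Barplot of within-pair species proportions
#'
#' Stacked base-graphics barplot of the share of mapped reads per species in
#' each primer pair, the usual way mixed-pool composition is displayed.
#'
#' @param table a `count_table`.
#' @param main plot title.
#' @return invisibly, the proportion matrix plotted.
#' @export
plot_count_proportions <- function(table, main = attr(table, "library_id")) {
  wide <- tapply(table$count, list(table$species, table$pair), sum)
  wide[is.na(wide)] <- 0
  prop <- sweep(wide, 2L, pmax(colSums(wide), 1), "/")
  graphics::barplot(prop, legend.text = rownames(prop), main = main,
                    ylab = "proportion of mapped reads", las = 1,
                    args.legend = list(x = "topright", cex = 0.6, bty = "n"))
  invisible(prop)
}
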