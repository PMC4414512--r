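#' Pipeline run configuration
#'
#' Collects every input and threshold of a full run in one validated object;
#' the whole configuration (and the seed) is echoed into the run manifest so
#' identical configurations give identical outputs.
#'
#' @param out_dir output directory (created if absent).
#' @param refs reference FASTA path, a data.frame from
#'   [read_reference_fasta()]/[synthetic_references()], or NULL to generate
#'   synthetic references for `species`.
#' @param species species set used when `refs` is NULL.
#' @param species_map optional id -> species sidecar (path or named vector).
#' @param primers a [primer_set()] or primer TSV path; defaults to
#'   [meat_primer_pairs()].
#' @param pool a [pool_spec()], a pool-spec YAML/JSON path, or the name of
#'   one of [meat_pools()].
#' @param reads optional FASTQ path of real reads; when NULL a library is
#'   simulated from `pool`.
#' @param n_reads reads to simulate.
#' @param seed integer seed for every stochastic step.
#' @param efficiency an [efficiency_model()].
#' @param error an [error_model()].
#' @param max_mismatch primer-site tolerance for panel building.
#' @param trim_max_mismatch primer-trim tolerance.
#' @param min_len,min_mapq retention thresholds.
#' @param min_reads,min_pairs detection thresholds.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, refs = NULL,
                       species = names(meat_species_classes()),
                       species_map = NULL, primers = NULL, pool = "c1",
                       reads = NULL, n_reads = 5000L, seed = 1L,
                       efficiency = efficiency_model(),
                       error = error_model(), max_mismatch = 3L,
                       trim_max_mismatch = 2L, min_len = 40L,
                       min_mapq = 20L, min_reads = 2L, min_pairs = 1L) {
  if (is.character(primers)) primers <- read_primers(primers)
  if (is.null(primers)) primers <- meat_primer_pairs()
  if (is.character(pool)) {
    pool <- if (file.exists(pool)) read_pool_spec(pool)
            else meat_pools()[[pool]] %||%
                 stop("unknown pool name: ", pool, call. = FALSE)
  }
  stopifnot(inherits(primers, "primer_set"), inherits(pool, "pool_spec"),
            n_reads > 0, min_reads >= 1, min_pairs >= 1)
  structure(list(out_dir = out_dir, refs = refs, species = species,
                 species_map = species_map, primers = primers, pool = pool,
                 reads = reads, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), efficiency = efficiency,
                 error = error, max_mismatch = as.integer(max_mismatch),
                 trim_max_mismatch = as.integer(trim_max_mismatch),
                 min_len = as.integer(min_len),
                 min_mapq = as.integer(min_mapq),
                 min_reads = as.integer(min_reads),
                 min_pairs = as.integer(min_pairs)),
            class = "run_config")
}

#' Run the full identification pipeline
#'
#' Orchestrates panel building, (optional) library simulation, primer
#' trimming and QC, glocal alignment with mapping-quality filtering, and
#' quantification. Every intermediate is persisted under `config$out_dir`
#' and a JSON manifest records the seed, all thresholds and per-stage read
#' counts; the stages conserve reads (trimmed in = retained + rejected).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `panel`, `reads`, `trimmed`, `qc`,
#'   `alignments`, `filtered`, `counts`, `error_rates`, `detection`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ampliconid] ", ...)
  outp <- function(f) file.path(config$out_dir, f)

  say("stage 1/5: reference panel")
  refs <- config$refs
  if (is.null(refs))
    refs <- synthetic_references(config$species, config$primers,
                                 seed = config$seed)
  else if (is.character(refs))
    refs <- read_reference_fasta(refs, config$species_map)
  panel <- build_panel(refs, config$primers, config$max_mismatch)
  write_panel(panel, outp("panel.fa"))
  write_panel_manifest(panel, outp("panel_manifest.tsv"))

  say("stage 2/5: reads")
  if (is.null(config$reads)) {
    sim <- simulate_library(config$pool, panel, config$efficiency,
                            config$error, config$n_reads,
                            seed = config$seed + 1L)
    reads <- sim$reads
    write_fastq(reads, outp("reads.fq"))
    write_truth(sim$truth, outp("truth.tsv"))
  } else {
    reads <- read_fastq(config$reads)
  }
  n_input <- nrow(reads)

  say("stage 3/5: trim + QC")
  qc <- quality_stats(reads)
  trimmed <- trim_primers(reads, config$primers, config$trim_max_mismatch)
  lf <- length_filter(trimmed, config$min_len)
  trimmed_kept <- lf$retained
  write_fastq(trimmed_kept[, c("read_id", "sequence", "qualities")],
              outp("trimmed.fq"))
  jsonlite::write_json(qc[c("n_reads", "called_nt", "q20_nt", "q20_pct")],
                       outp("qc.json"), auto_unbox = TRUE, digits = NA)

  say("stage 4/5: align")
  scoring <- alignment_scoring(min_mapq = config$min_mapq,
                               min_len = config$min_len)
  aln <- map_reads(trimmed_kept, panel, scoring)
  flt <- filter_alignments(aln, scoring)
  write_sam(aln, trimmed_kept, panel, outp("alignments.sam"))
  if (nrow(aln) != nrow(flt$retained) + sum(flt$rejected))
    stop("read conservation violated in stage align", call. = FALSE)

  say("stage 5/5: quantify")
  unassigned <- n_input - nrow(flt$retained)
  counts <- count_by_region(flt$retained,
                            library_id = config$pool$name,
                            panel = panel, unassigned = unassigned)
  err_tab <- estimate_error_rates(flt$retained)
  detect <- call_species(counts, config$min_reads, config$min_pairs,
                         species = unique(panel$species))
  write_tsv_table(counts, outp("counts.tsv"))
  write_tsv_table(err_tab, outp("error_rates.tsv"))
  write_tsv_table(detect, outp("detection.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ampliconid")),
    seed = config$seed,
    thresholds = config[c("max_mismatch", "trim_max_mismatch", "min_len",
                          "min_mapq", "min_reads", "min_pairs")],
    pool = config$pool$name,
    reads = list(input = n_input,
                 length_filtered = lf$n_rejected,
                 aligned_input = nrow(trimmed_kept),
                 retained = nrow(flt$retained),
                 rejected = as.list(flt$rejected),
                 counted = sum(counts$count),
                 unassigned = unassigned))
  if (manifest$reads$counted + manifest$reads$length_filtered +
      sum(flt$rejected) != n_input)
    stop("read conservation violated across the pipeline", call. = FALSE)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  say("done: ", n_input, " reads in, ", sum(counts$count), " counted")
  invisible(list(panel = panel, reads = reads, trimmed = trimmed_kept,
                 qc = qc, alignments = aln, filtered = flt,
                 counts = counts, error_rates = err_tab,
                 detection = detect, manifest = manifest))
}
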