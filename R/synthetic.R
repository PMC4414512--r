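#' Synthetic mitochondrial reference sequences
#'
#' Generates a fully synthetic stand-in for a multi-species mitochondrial
#' reference set: for each primer pair an ancestral target sequence is drawn,
#' each species receives its own diverged copy (independent substitutions at
#' `divergence` per site) with a species-specific target length inside the
#' pair's published amplicon-size range, and the three primer-flanked
#' amplicons are concatenated with random spacer into one reference per
#' species. Avian species optionally carry mismatches inside their primer
#' annealing sites, mimicking universal primers designed on mammalian
#' alignments. No real sequence data is used.
#'
#' @param species character vector of species labels.
#' @param pairs a [primer_set()].
#' @param divergence per-site substitution probability from the ancestor
#'   (default 0.1 gives ~18% pairwise divergence, ample for assignment).
#' @param avian_primer_mismatches named integer vector (pair name -> number
#'   of mismatches injected into each primer site of avian species).
#' @param flank random bases placed before/after each amplicon.
#' @param seed integer seed; the generator is deterministic given it.
#' @param classes species -> class map used to pick the avian species.
#' @param drop optional character vector of `"species|pair"` keys whose
#'   primer sites are destroyed (simulates a pair failing on a taxon).
#' @return data.frame with `source_id`, `species`, `sequence`, ready for
#'   [build_panel()].
#' @export
#' @examples
#' refs <- synthetic_references(c("pig", "cattle", "chicken"), seed = 1)
#' nrow(refs)
synthetic_references <- function(species = names(meat_species_classes()),
                                 pairs = meat_primer_pairs(),
                                 divergence = 0.1,
                                 avian_primer_mismatches =
                                   c("12S_KH" = 1L, "16S_KH" = 1L,
                                     "16S_Ki" = 2L),
                                 flank = 30L, seed = 101L,
                                 classes = meat_species_classes(),
                                 drop = character(0)) {
  stopifnot(length(species) >= 1L, inherits(pairs, "primer_set"),
            divergence >= 0, divergence < 1)
  with_seed(seed, {
    ancestors <- lapply(pairs, function(p) {
      tmax <- p$len_range[2L] - nchar(p$forward) - nchar(p$reverse)
      if (is.na(tmax)) tmax <- 180L
      random_dna(tmax)
    })
    out <- lapply(species, function(sp) {
      blocks <- character(0)
      for (p in pairs) {
        key <- paste(sp, p$name, sep = "|")
        tmin <- p$len_range[1L] - nchar(p$forward) - nchar(p$reverse)
        tmax <- p$len_range[2L] - nchar(p$forward) - nchar(p$reverse)
        if (is.na(tmin)) { tmin <- 160L; tmax <- 180L }
        tlen <- sample(tmin:tmax, 1L)
        target <- substr(mutate_dna(ancestors[[p$name]], divergence), 1L, tlen)
        fw_site <- p$forward
        rv_site <- revcomp(p$reverse)
        if (identical(unname(classes[sp]), "avian")) {
          nmm <- unname(avian_primer_mismatches[p$name])
          if (!is.na(nmm) && nmm > 0L) {
            fw_site <- mutate_dna_n(fw_site, nmm)
            rv_site <- mutate_dna_n(rv_site, nmm)
          }
        }
        if (key %in% drop) next
        blocks <- c(blocks, paste0(random_dna(flank), fw_site, target,
                                   rv_site, random_dna(flank)))
      }
      paste(blocks, collapse = random_dna(20L))
    })
    data.frame(source_id = paste0("syn_", species), species = species,
               sequence = unlist(out), stringsAsFactors = FALSE)
  })
}

#' Run code with a temporary RNG seed, restoring global RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each site independently with probability `rate`
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# substitute exactly n distinct sites
mutate_dna_n <- function(x, n) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  for (i in sample(seq_along(chars), min(n, length(chars))))
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}
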