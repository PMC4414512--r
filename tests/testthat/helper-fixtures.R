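# Shared fixtures, built in code at test time.

# small three-species panel over the three standard primer pairs
fixture_panel <- function(species = c("pig", "cattle", "chicken"),
                          seed = 11) {
  refs <- synthetic_references(species, seed = seed)
  suppressWarnings(build_panel(refs, meat_primer_pairs()))
}

# assemble the exact amplicon a simulated read should carry
fixture_amplicon <- function(panel, species, pair_name,
                             pairs = meat_primer_pairs()) {
  p <- pairs[[pair_name]]
  t <- panel$target_seq[panel$species == species & panel$pair == pair_name]
  paste0(p$forward, t, revcomp(p$reverse))
}

as_reads <- function(seqs, qual_char = "I") {
  data.frame(read_id = sprintf("r%04d", seq_along(seqs)), sequence = seqs,
             qualities = strrep(qual_char, nchar(seqs)),
             stringsAsFactors = FALSE)
}
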