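# ampliconid

Identification of meat species in DNA mixtures from multi-primer
mitochondrial amplicon sequencing.

Food-fraud surveillance, forensics and wildlife work all face the same
question: *which species contributed DNA to this sample?* One flexible
answer is DNA metabarcoding with **universal primers** — primer pairs
sitting in conserved flanks of the mitochondrial 12S and 16S rRNA genes,
bracketing internal regions that differ between species — so a single PCR
amplifies a species-informative fragment from mammals and birds alike.
The pooled amplicons are sequenced on a benchtop semiconductor instrument
and every read is assigned to a species by alignment against a reference
panel of target regions. Several primer pairs are used in parallel so that
one pair failing on a taxon (primer–template mismatches, PCR competition)
does not make that species invisible.

`ampliconid` is a self-contained R implementation of that workflow, for
method developers and analysts who want to run, stress-test or extend the
analysis without external aligners or access to the original sequencing
runs:

* **Reference panels** — in-silico PCR (`find_primer_sites()`,
  `in_silico_pcr()`, `build_panel()`) locates degenerate-primer binding
  sites under IUPAC-aware comparison and extracts between-primer target
  regions; `discriminability_report()` quantifies how well a marker
  separates the panel's species.
* **Simulation** — `simulate_library()` draws reads multinomially from a
  DNA pool specification (mass × amplification efficiency, normalized per
  primer pair) and applies a semiconductor-style error model: uniform
  substitutions plus ±1 homopolymer run-length errors whose probability
  grows with run length. Every read carries a ground-truth record.
* **Preprocessing** — barcode demultiplexing, primer trimming from both
  read ends, Q20 statistics, minimum-length filter.
* **Alignment** — a glocal (read-global, reference-local) affine-gap
  aligner in C++ scores each read against every region on both strands.
  Read retention requires length ≥ 40 nt and
  `MAPQ = min(60, 6 · (S_best − S_second)) ≥ 20`; ties are filtered, never
  randomly assigned. SAM output included.
* **Quantification** — per-region count tables, per-species aggregation,
  reads-per-nanogram normalization, per-base error rates
  ((mismatches + indel bases) / aligned reference bases), replicate
  Pearson correlations with degenerate-slice flagging, and threshold-based
  species detection calls.
* **Orchestration** — `run_pipeline()` chains the stages with a manifest
  recording seed, thresholds and per-stage read conservation;
  `exec/ampliconid.R` exposes each stage as a shell subcommand.

The three bundled primer pairs (`meat_primer_pairs()`), the six DNA pool
designs (`meat_pools()`, including 1:10 and 1:50 pig/horse dilutions) and
a published dilution-series count table (`dilution_series_counts()`) mirror
the experimental design the package models. Reference sequences are not
bundled; `synthetic_references()` generates a fully synthetic panel for
testing, and real references can be supplied as FASTA with species labels.

## Worked example

A four-species panel with pig and horse diluted 1:10 relative to cattle
and chicken:

```r
library(ampliconid)

refs  <- synthetic_references(c("pig", "horse", "cattle", "chicken"), seed = 42)
panel <- build_panel(refs, meat_primer_pairs())

pool <- pool_spec("demo", c(pig = 10, horse = 10, cattle = 100, chicken = 100))
sim  <- simulate_library(pool, panel, n_reads = 4000, seed = 7)

kept <- length_filter(trim_primers(sim$reads, meat_primer_pairs()))$retained
flt  <- filter_alignments(map_reads(kept, panel))
counts <- count_by_region(flt$retained, "demo", panel = panel,
                          unassigned = 4000 - nrow(flt$retained))
print(counts)
#> Count table for demo - 4000 assigned reads, 0 unassigned
#>         12S_KH 16S_KH 16S_Ki
#> cattle     611    598    599
#> chicken    625    635    572
#> horse       65     50     55
#> pig         68     60     62

call_species(counts, min_reads = 2, min_pairs = 2)[, 1:4]
#>   species detected n_supporting_pairs     supporting_pairs
#> 1     pig     TRUE                  3 12S_KH,16S_KH,16S_Ki
#> 2   horse     TRUE                  3 12S_KH,16S_KH,16S_Ki
#> 3  cattle     TRUE                  3 12S_KH,16S_KH,16S_Ki
#> 4 chicken     TRUE                  3 12S_KH,16S_KH,16S_Ki
```

Each primer pair contributes ~1/3 of the library (amplicons are mixed at
equal volume); within a pair, counts are proportional to DNA mass, so the
1:10 species sit near 60 reads against ~600 for the majority species — and
are still called confidently in all three pairs at a 2-read threshold.
Per-pair error rates under the default error model land around 0.004
errors per aligned base, inside the band observed on real semiconductor
amplicon runs:

```r
round(attr(estimate_error_rates(flt$retained), "pair_rates"), 4)
#> 12S_KH 16S_KH 16S_Ki
#> 0.0043 0.0048 0.0040
```

The same analysis runs from the shell:

```sh
Rscript exec/ampliconid.R run --pool c1 --n 5000 --seed 1 --out-dir run_out
```

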