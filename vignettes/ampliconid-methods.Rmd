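---
title: "Methods: amplicon-based meat species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon-based meat species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Meat products are routinely adulterated or mislabelled, and the species of
origin of a DNA mixture cannot be resolved by assays that test one species
at a time. A multiplex alternative is to PCR-amplify short mitochondrial
rRNA fragments (12S and 16S) with *universal* primer pairs — primers sitting
in flanks conserved across mammals and birds, bracketing an internal region
that differs between species — sequence the pooled amplicons on a benchtop
semiconductor instrument, and assign each read to a species by alignment
against a reference panel of the expected target regions. Using several
primer pairs at once hedges against any single pair failing on some taxon
through primer–template mismatches or PCR competition.

`ampliconid` implements that whole workflow in one package: panel
construction by in-silico PCR, a read simulator that stands in for the
wet-lab and sequencing steps, primer trimming and quality statistics,
glocal alignment with a mapping-quality gate, and the downstream count,
error-rate, correlation and detection summaries.

## Reference panel construction

A `primer_pair` stores both oligos 5'→3' as synthesized; the reverse primer
is the reverse complement of the template top strand. `find_primer_sites()`
scans every window of a reference under IUPAC-aware Hamming comparison:
an ambiguity code matches any base it denotes at zero cost, the standard
semantics for degenerate primers. `in_silico_pcr()` pairs the best forward
site with a compatible downstream reverse site on either strand, preferring
fewest total primer mismatches, then the shortest product, then the
leftmost plus-strand site. The stored target region *excludes* both
primers, because reads are primer-trimmed before alignment; alignment
coordinates are 0-based half-open on the scanned strand throughout.

Two tolerances matter:

* `max_mismatch` (default 3) for primer-site discovery. Universal pairs
  designed on mammalian alignments are known to anneal to avian templates
  despite several mismatches, so a tolerance of 0 would wrongly drop avian
  regions. The value used by the original reference construction is not
  documented anywhere we could verify, so it is exposed as a parameter
  rather than asserted.
* 3'-end mismatches are *not* specially weighted. Polymerase extension is
  more sensitive to 3' mismatches, but no quantitative model is available
  for these primer sets; this simplification is deliberate.

`discriminability_report()` replaces tree building as the check that a
marker separates the panel's species: it reports pairwise p-distances
(mismatches plus gap columns over aligned columns, from glocal alignment of
the shorter sequence onto the longer) and their minimum. A positive minimum
is the precondition for unambiguous assignment. When two sequences admit
several equal-score alignments the decomposition into mismatches and gaps
is not unique; distances are then reported from the aligner's
deterministic traceback.

## The DNA pool model

A `pool_spec` records nanograms of each species in the pooled stock and the
total mass drawn into one PCR (20 ng in the design the package mirrors).
The per-reaction mass of species $s$ is

$$ m_s = 20\,\mathrm{ng} \times \frac{\text{ng}_s}{\sum_t \text{ng}_t}. $$

The six bundled pools (`meat_pools()`) are: seven mammals equimolar (a),
six birds equimolar (b), all 13 species equimolar in duplicate (c1, c2),
and the mammalian pool with pig and horse at 1/10 (d) or 1/50 (e). Under
the formula, pool c gives 20/13 ≈ 1.54 ng per species and pool e gives
0.079 ng for each minor species. (The published description of the 1:10
and 1:50 reactions prints "about 0.28 ng and 0.09 ng", which is not
consistent with its own mass-share arithmetic; the package follows the
arithmetic, which does reproduce the printed values for the equimolar
pools.)

## Amplification efficiency and read allocation

Amplicons from the different pairs are mixed at equal volume, so each pair
contributes the same expected read mass to a library. Within a pair, the
probability that a read originates from species $s$ is

$$ P(s \mid p) \;\propto\; m_s \, e_{s,p}, $$

where $e_{s,p} \ge 0$ is a multiplicative amplification efficiency. By
default every efficiency is 1. `efficiency_from_panel()` derives
heterogeneous efficiencies from the primer-site mismatches recorded during
panel construction, $e_{s,p} = f^{\,\mathrm{mm}_{fwd} + \mathrm{mm}_{rev}}$
with decay $f = 0.5$ per mismatch; with the default synthetic references
this yields the mammal-dominated composition seen in real mixed pools, and
setting an efficiency to exactly 0 models the PCR-competition dropout of
avian templates for one 16S pair. The value 0.5 is a plausibility choice,
not a fitted constant.

## Sequencing error model

Semiconductor sequencing reads homopolymer runs from a single incorporation
signal, so its characteristic error is a ±1 run-length error, growing with
run length; uniform substitutions cover the remaining PCR and base-calling
errors. `error_model()` therefore has two parts:

* `sub_rate` — per-base substitution probability, default 0.002;
* `hp_indel_rate(L)` — probability that a maximal run of length $L \ge 2$
  gains or loses one base (direction equiprobable), default
  $\min(0.01\,(L-1),\,0.2)$, forced non-decreasing in $L$.

The defaults are a calibration, not ground truth: they place simulated
per-(species, pair) error rates inside the 0.0003–0.0181 per-base band
reported for real runs of this assay, with the package's default amplicons.
Substitutions are applied first; runs are then re-identified on the
substituted sequence. Errors are applied to the *target region only* and
primer bases are emitted exactly. This is what keeps the truth table
exactly recoverable: the per-read event counts equal what re-alignment of
the trimmed read against its source region finds. The two exceptions are
genuine ambiguities of alignment, not of bookkeeping: events in adjacent
homopolymer runs can cancel into a cheaper apparent substitution, and a
deletion in the first or last run of a target is absorbed by the glocal
aligner's free reference ends as a shorter clean alignment.
Robustness of trimming to primer-end errors is exercised separately with
purpose-built reads.

Reads are simulated full-length — no fragmentation — so mapped-read counts
estimate amplicon abundance directly. Clonal (PCR-duplicate) structure and
chimeras are not modelled; each read is an independent draw. A constant
Phred score (default 28) stands in for the per-base quality profile, since
the pipeline's only quality-dependent decisions (Q20 accounting, optional
3' quality trim) are exercised with explicitly constructed qualities in
tests.

## Trimming, demultiplexing and the length gate

`trim_primers()` compares each pair's entry primer against the read's 5'
end and the partner's reverse complement against the 3' end (both
orientations, Hamming only — indels inside a 20-mer primer match are rare
enough that tolerating two mismatches, the default, recovers simulated and
lightly damaged primers while keeping the comparison trivially auditable).
Each end is clipped independently, so a truncated read still loses its 5'
primer; unmatched reads pass through flagged rather than being dropped,
and the aligner's free reference ends absorb any residual primer bases.
`demultiplex()` requires barcode sets with pairwise Hamming distance
greater than twice the tolerance, which makes ambiguous assignment
impossible by construction; anything not matching exactly one barcode goes
to the unassigned bin.

After trimming, reads shorter than 40 nt are discarded (`length_filter()`,
inclusive threshold). The 40 nt value is interpreted as *post-trim read
length*, since the filter follows trimming in the pipeline definition; an
aligned-length variant would be stricter and is not the default.

## Glocal alignment and mapping quality

Assignment uses read-global, reference-local ("glocal") dynamic
programming: the read must align end to end, while reference bases outside
the aligned window are free — exactly the geometry of a full-length
amplicon read against a short reference region. Scoring is affine:
match +1, mismatch −4, gap of length $k$ costs $6 + k$. These mirror
widely used short-read defaults; nothing in the package is sensitive to
the exact values as long as mismatches are several times the match reward.
Traceback is deterministic with tie order diagonal > up (insertion) > left
(deletion), and end-column ties resolve to the fewest reference bases.

Every read is aligned against every region on both strands. Uniqueness of
the best hit is scored as

$$ \mathrm{MAPQ} = \min\{60,\; 6\,(S_{best} - S_{second})\}, $$

a deliberate, documented surrogate for aligner-specific estimators: the
downstream filter only needs a monotone uniqueness score with a ≥ 20 gate.
Exact ties give MAPQ 0 and are filtered, never randomly assigned — in this
application a misassigned species is the costly error. Retention requires
read length ≥ 40 *and* MAPQ ≥ 20, both inclusive.

The C++ search prunes candidates that provably cannot come within 10 score
units of the best hit (10 = 60/6, the saturation margin of the MAPQ
formula), using exact score upper bounds; pruning therefore never changes
an assignment or a MAPQ value, and `second_best` is reported exactly
whenever it is within that margin (NA otherwise). A k-mer probe ordering
decides only the order in which candidates are examined. Correctness
against an independent naive full-matrix DP is asserted on a thousand
random instances in the test suite and recomputed by the acceptance
script.

## Quantification

`count_by_region()` increments one cell per retained read — the in-memory
equivalent of counting alignments per reference — with explicit zeros for
panel cells without reads, and read conservation (counted + unassigned =
input) checked across the pipeline. Error rates per (species, pair) divide
substitutions *plus inserted and deleted bases* by aligned reference
bases; indel bases are included by default because homopolymer indels
dominate this platform's errors, and a substitutions-only mode exists for
sensitivity analysis. The reference-base denominator keeps rates in [0, 1]
under deletions.

Replicate agreement is summarized by Pearson correlation on raw counts
(not proportions), over all cells and sliced by species class and primer
pair; slices where either library is constant — an all-zero avian column,
say — are flagged degenerate instead of contributing a meaningless 1.000.
For the bundled dilution-series tables both the 15-cell (shared species)
and full 21-cell correlations are exposed, since the published description
of which cells entered the computation is ambiguous.

`call_species()` declares a species present when at least `min_pairs`
primer pairs each hold at least `min_reads` reads. No community threshold
exists for separating a trace component from background, so both knobs are
prominent and default low (`min_reads = 2`, `min_pairs = 1`); detection is
monotone non-increasing in `min_reads`, which the tests assert on a
simulated 1:50 pool.

## The synthetic reference generator

No real mitochondrial sequences ship with the package.
`synthetic_references()` draws, per primer pair, an ancestral target and
gives each species an independently mutated copy (default 10% per site,
about 18% pairwise divergence — looser than real 12S/16S divergence
between, say, closely related galliforms, and deliberately easy to
separate) with a species-specific length inside the pair's published
product-size range. Avian species receive one mismatch in each 12S/16S
primer site and two in each site of the third pair, mimicking primers
designed on mammalian alignments. What the generator does *not* emulate:
real phylogenetic structure (closely related species pairs), intraspecific
variants, length polymorphism beyond the published ranges, chimeric reads,
and realistic per-base quality profiles. Passing tests therefore
demonstrate that the pipeline machinery is correct and sensitive under
controlled conditions, not that real 12S/16S markers separate any
particular pair of taxa — that question is answered per panel by
`discriminability_report()` on real references.

## Problem sizes and reproducibility

The test suite and the acceptance script exercise the full chain at 10–50
thousand reads per library against the 13-species synthetic panel (39
regions), sizes chosen so that every statistical check — multinomial
goodness of fit, binomial error-rate recovery at 0.005 over ≥ 50,000
aligned bases, detection of 1:50 minor components, replicate correlation —
has comfortable power on a single CPU. Every stochastic step takes an
explicit integer seed, a library simulated twice with the same seed is
byte-identical, and the pipeline manifest echoes the seed and every
threshold of the run.

## Known limitations

* Mixture *proportions* are not formally estimated; counts per nanogram
  are a rough efficiency comparison, not a calibrated quantification, and
  mtDNA copy number per tissue is outside the model.
* The MAPQ surrogate is not comparable numerically to any specific
  aligner's estimator; only its ≥ 20 gate is meaningful.
* Hamming-only primer trimming will miss primers carrying indels.
* The efficiency model ties amplification loss to primer-site mismatch
  counts only; real PCR competition also depends on template abundance and
  fragment length.
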