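test_that("demultiplexing assigns, clips and conserves reads", {
  set.seed(61)
  barcodes <- c(bc1 = "ACGTACGTAG", bc2 = "TTGGCCTTAA", bc3 = "GACTGACTCC",
                bc4 = "CATGCATGGT", bc5 = "TGCATGCAAC", bc6 = "GTACGTACTG")
  inner <- vapply(1:60, function(i) random_seq(50), "")
  bc_of <- rep(names(barcodes), each = 10)
  reads <- as_reads(paste0(barcodes[bc_of], inner))
  dm <- demultiplex(reads, barcodes, max_mismatch = 1)
  expect_equal(vapply(dm$bins, nrow, integer(1)),
               setNames(rep(10L, 6), names(barcodes)))
  expect_equal(nrow(dm$unassigned), 0L)
  expect_identical(dm$bins$bc1$sequence, inner[bc_of == "bc1"])
  # quality strings clipped in register
  expect_equal(nchar(dm$bins$bc1$qualities), nchar(dm$bins$bc1$sequence))

  # one barcode error still assigns; garbage goes unassigned
  err_read <- as_reads(paste0("CCGTACGTAG", inner[1]))   # bc1 with 1 error
  none <- as_reads(paste0("AAAAAAAAAA", inner[2]))
  dm2 <- demultiplex(rbind(err_read, none), barcodes, max_mismatch = 1)
  expect_equal(nrow(dm2$bins$bc1), 1L)
  expect_identical(dm2$bins$bc1$sequence, inner[1])
  expect_equal(nrow(dm2$unassigned), 1L)
  tot <- sum(vapply(dm2$bins, nrow, integer(1))) + nrow(dm2$unassigned)
  expect_equal(tot, 2L)

  # barcode sets too close for the tolerance are a configuration error
  expect_error(demultiplex(reads, c(a = "ACGTACGTAG", b = "ACGTACGTAC"),
                           max_mismatch = 1), "mismatches apart")
})

test_that("primer trimming clips both ends and identifies the pair", {
  pairs <- meat_primer_pairs()
  pp <- pairs[["16S_KH"]]
  set.seed(62)
  target <- random_seq(75)
  full <- paste0(pp$forward, target, revcomp(pp$reverse))
  tr <- trim_primers(as_reads(full), pairs)
  expect_identical(tr$sequence, target)
  expect_equal(tr$pair, "16S_KH")
  expect_true(tr$trimmed_fwd && tr$trimmed_rev)
  expect_equal(tr$orientation, "+")
  expect_equal(nchar(tr$qualities), nchar(tr$sequence))

  # reverse-strand read: starts with the reverse primer as synthesized
  trr <- trim_primers(as_reads(revcomp(full)), pairs)
  expect_identical(trr$sequence, revcomp(target))
  expect_equal(trr$orientation, "-")

  # truncated read missing the 3' primer loses only its 5' end
  trunc <- substr(full, 1, nchar(pp$forward) + 40)
  tr3 <- trim_primers(as_reads(trunc), pairs)
  expect_true(tr3$trimmed_fwd)
  expect_false(tr3$trimmed_rev)
  expect_identical(tr3$sequence, substr(target, 1, 40))

  # unmatched reads pass through flagged, not dropped
  noise <- trim_primers(as_reads(random_seq(80)), pairs)
  expect_true(is.na(noise$pair))
  expect_false(noise$trimmed_fwd || noise$trimmed_rev)
  expect_equal(nchar(noise$sequence), 80L)
})

test_that("trimming tolerates primer mismatches, verified by brute force", {
  pairs <- meat_primer_pairs()
  pp <- pairs[["12S_KH"]]
  set.seed(63)
  target <- random_seq(100)
  fw <- pp$forward; rc <- revcomp(pp$reverse)
  substr(fw, 7, 7) <- if (substr(fw, 7, 7) == "A") "G" else "A"
  substr(rc, 3, 3) <- if (substr(rc, 3, 3) == "C") "T" else "C"
  read <- paste0(fw, target, rc)
  expect_equal(oracle_end_mismatch(read, pp$forward), 1L)
  expect_equal(oracle_end_mismatch(read, revcomp(pp$reverse),
                                   from_end = TRUE), 1L)
  tr <- trim_primers(as_reads(read), pairs, max_mismatch = 2)
  expect_identical(tr$sequence, target)
  expect_true(tr$trimmed_fwd && tr$trimmed_rev)
  # beyond tolerance the end is left alone
  tr0 <- trim_primers(as_reads(read), pairs, max_mismatch = 0)
  expect_false(tr0$trimmed_fwd)
})

test_that("trimming is idempotent on simulated libraries", {
  panel <- fixture_panel()
  pool <- pool_spec("mix", setNames(rep(100, 3), unique(panel$species)))
  sim <- simulate_library(pool, panel, n_reads = 120, seed = 64)
  t1 <- trim_primers(sim$reads, meat_primer_pairs())
  t2 <- trim_primers(t1[, c("read_id", "sequence", "qualities")],
                     meat_primer_pairs())
  expect_identical(t2$sequence, t1$sequence)
  expect_identical(t2$qualities, t1$qualities)
})

test_that("Q20 statistics reproduce the run-level arithmetic", {
  expect_equal(q20_percent(33294511, 29109688), 87.43)
  expect_equal(q20_percent(1000, 1000), 100)
  expect_error(q20_percent(0, 0), "positive")
  expect_error(q20_percent(10, 11), "q20_nt")

  # boundary: Q20 means Phred >= 20
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = strrep("A", c(500, 500)),
                      qualities = c(strrep(intToUtf8(19 + 33), 500),
                                    strrep(intToUtf8(20 + 33), 500)),
                      stringsAsFactors = FALSE)
  qs <- quality_stats(reads)
  expect_equal(qs$called_nt, 1000L)
  expect_equal(qs$q20_nt, 500L)
  expect_equal(qs$q20_pct, 50)

  all30 <- data.frame(read_id = "c", sequence = strrep("A", 100),
                      qualities = strrep(intToUtf8(30 + 33), 100),
                      stringsAsFactors = FALSE)
  expect_equal(quality_stats(all30)$q20_pct, 100)
})

test_that("per-barcode QC breakdown reconciles with totals", {
  set.seed(65)
  barcodes <- c(x = "ACGTACGTAG", y = "TTGGCCTTAA")
  reads <- as_reads(paste0(rep(barcodes, each = 5),
                           vapply(1:10, function(i) random_seq(40), "")))
  dm <- demultiplex(reads, barcodes)
  qs <- quality_stats(dm)
  expect_equal(nrow(qs$per_barcode), 2L)
  expect_equal(qs$n_reads, 10L)
  # clipped barcodes are not counted as called bases in the bins
  expect_equal(sum(qs$per_barcode$called_nt), 10 * 40)
})

test_that("the length filter is inclusive at the boundary", {
  reads <- as_reads(vapply(c(39, 40, 41), random_seq, ""))
  lf <- length_filter(reads, 40)
  expect_equal(nchar(lf$retained$sequence), c(40L, 41L))
  expect_equal(lf$n_rejected, 1L)
  empty <- length_filter(reads[0, ], 40)
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(empty$n_rejected, 0L)
})

test_that("trimmed short-amplicon reads survive the length filter", {
  # shortest marker: full product 112-121 bp minus 21+18 primer bases
  # leaves 73-82 nt, comfortably above the 40 nt gate
  panel <- fixture_panel()
  pool <- pool_spec("mix", setNames(rep(100, 3), unique(panel$species)))
  sim <- simulate_library(pool, panel, n_reads = 500, seed = 66)
  keep <- sim$truth$pair == "16S_KH"
  tr <- trim_primers(sim$reads[keep, ], meat_primer_pairs())
  expect_true(all(nchar(tr$sequence) >= 70 & nchar(tr$sequence) <= 85))
  lf <- length_filter(tr, 40)
  expect_equal(lf$n_rejected, 0L)
})

test_that("barcoded libraries demultiplex cleanly before trimming", {
  panel <- fixture_panel()
  pool <- pool_spec("mix", setNames(rep(100, 3), unique(panel$species)))
  s1 <- simulate_library(pool, panel, n_reads = 40, seed = 67,
                         barcode = "ACGTACGTAG", read_id_prefix = "l1")
  s2 <- simulate_library(pool, panel, n_reads = 40, seed = 68,
                         barcode = "TTGGCCTTAA", read_id_prefix = "l2")
  dm <- demultiplex(rbind(s1$reads, s2$reads),
                    c(lib1 = "ACGTACGTAG", lib2 = "TTGGCCTTAA"))
  expect_equal(nrow(dm$bins$lib1), 40L)
  expect_equal(nrow(dm$bins$lib2), 40L)
  expect_equal(nrow(dm$unassigned), 0L)
  # barcode clipped on both strands: trimming then works as usual
  tr <- trim_primers(dm$bins$lib1, meat_primer_pairs())
  expect_true(all(tr$trimmed_fwd & tr$trimmed_rev))
})
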