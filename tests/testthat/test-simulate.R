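test_that("per-reaction masses follow the pool arithmetic", {
  pools <- meat_pools()
  # 13-species equimolar pool: 20/13 ~ 1.5 ng per species
  ngc <- per_reaction_ng(pools$c1)
  expect_equal(unname(ngc["pig"]), 20 / 13)
  expect_lt(abs(ngc[["pig"]] - 1.5), 0.05)
  # 1:10 pool: pig share 10/520; 1:50 pool: pig share 2/504
  expect_equal(unname(per_reaction_ng(pools$d)["pig"]), 20 * 10 / 520)
  expect_equal(unname(per_reaction_ng(pools$e)["pig"]), 20 * 2 / 504)
  expect_equal(sum(per_reaction_ng(pools$e)), 20)
})

test_that("expected read weights normalize per pair", {
  panel <- suppressWarnings(
    build_panel(synthetic_references(seed = 11), meat_primer_pairs()))
  pools <- meat_pools()

  # pool d under uniform efficiency: pig probability 10/520 in every pair
  w <- expected_read_weights(pools$d, panel)
  for (p in unique(w$pair)) {
    wp <- w[w$pair == p, ]
    expect_equal(sum(wp$prob), 1)
    expect_equal(wp$prob[wp$species == "pig"], 10 / 520)
  }
  # pool e: combined minor-species share 2/252 per pair
  we <- expected_read_weights(pools$e, panel)
  for (p in unique(we$pair)) {
    minor <- sum(we$prob[we$pair == p & we$species %in% c("pig", "horse")])
    expect_equal(minor, 2 / 252)
  }

  # single-species pool concentrates all probability
  w1 <- expected_read_weights(pool_spec("solo", c(pig = 100)), panel)
  expect_true(all(w1$prob == 1))

  # zeroed avian efficiency removes avian reads and renormalizes mammals
  cls <- meat_species_classes()
  eff0 <- set_efficiency(efficiency_model(), names(cls)[cls == "avian"],
                         "16S_Ki", 0)
  wz <- expected_read_weights(pools$c1, panel, eff0)
  ki <- wz[wz$pair == "16S_Ki", ]
  expect_equal(sum(ki$prob[ki$species %in% names(cls)[cls == "avian"]]), 0)
  expect_equal(sum(ki$prob), 1)
  expect_equal(ki$prob[ki$species == "pig"], 1 / 7)
  expect_error(
    expected_read_weights(pool_spec("bad", c(zebra = 1)), panel),
    "zebra")
})

test_that("the error model applies substitutions and homopolymer indels", {
  clean <- error_model(sub_rate = 0, hp_indel_rate = function(L) rep(0, length(L)))
  set.seed(41)
  seq <- random_seq(200)
  out <- apply_error_model(seq, clean)
  expect_identical(out$sequence, seq)
  expect_equal(nrow(out$script), 0L)

  # a run of four with certain indel changes length by exactly one
  certain <- error_model(sub_rate = 0, hp_indel_rate = function(L)
    as.numeric(L >= 4))
  set.seed(42)
  hits <- replicate(40, {
    r <- apply_error_model("GGAAAACC", certain)
    expect_true(nchar(r$sequence) %in% c(7L, 9L))
    expect_equal(r$n_ins + r$n_del, 1L)
    expect_equal(r$script$pos, 3L)   # run start after the GG
    nchar(r$sequence)
  })
  expect_setequal(unique(hits), c(7L, 9L))  # both directions occur

  # monotonicity of the rate function is enforced
  expect_error(error_model(hp_indel_rate = function(L) 0.2 - 0.01 * L),
               "non-decreasing")

  # substitution count is binomial: 10^6 bases within 3 sigma
  homopolymer_free <- paste(rep("ACGT", 250), collapse = "")
  submod <- error_model(sub_rate = 0.005,
                        hp_indel_rate = function(L) rep(0, length(L)))
  set.seed(43)
  nsub <- sum(replicate(1000, apply_error_model(homopolymer_free, submod)$n_sub))
  expected <- 1e6 * 0.005
  sigma <- sqrt(1e6 * 0.005 * 0.995)
  expect_lt(abs(nsub - expected), 3 * sigma)
})

test_that("simulated libraries are deterministic and error-free when asked", {
  panel <- fixture_panel()
  pool <- pool_spec("solo", c(pig = 100))
  clean <- error_model(sub_rate = 0, hp_indel_rate = function(L) rep(0, length(L)))
  sim <- simulate_library(pool, panel, err = clean, n_reads = 200, seed = 7)
  expected <- vapply(sim$truth$pair, function(p)
    fixture_amplicon(panel, "pig", p), "")
  minus <- sim$truth$strand == "-"
  expected[minus] <- revcomp(expected[minus])
  expect_identical(sim$reads$sequence, unname(expected))
  expect_true(all(sim$truth$n_sub + sim$truth$n_ins + sim$truth$n_del == 0))

  sim2 <- simulate_library(pool, panel, err = clean, n_reads = 200, seed = 7)
  expect_identical(sim, sim2)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(sim$reads, f1); write_fastq(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  sim3 <- simulate_library(pool, panel, err = clean, n_reads = 200, seed = 8)
  expect_false(identical(sim$reads$sequence, sim3$reads$sequence))
})

test_that("read origins follow the multinomial allocation", {
  panel <- suppressWarnings(
    build_panel(synthetic_references(seed = 11), meat_primer_pairs()))
  pool <- meat_pools()$d
  sim <- simulate_library(pool, panel, n_reads = 20000, seed = 9)
  w <- expected_read_weights(pool, panel)
  key <- paste(w$species, w$pair)
  obs <- table(factor(paste(sim$truth$species, sim$truth$pair),
                      levels = key))
  gof <- chisq.test(as.integer(obs), p = w$prob / length(unique(w$pair)))
  expect_gt(gof$p.value, 0.01)
})

test_that("truth-table events are recoverable by re-alignment", {
  panel <- fixture_panel()
  pool <- pool_spec("mix", setNames(rep(100, 3), unique(panel$species)))

  # substitutions only: per-read mismatch counts match exactly
  submod <- error_model(sub_rate = 0.01,
                        hp_indel_rate = function(L) rep(0, length(L)))
  sim <- simulate_library(pool, panel, err = submod, n_reads = 150,
                          seed = 51)
  tr <- trim_primers(sim$reads, meat_primer_pairs())
  key <- paste(panel$species, panel$pair, sep = "|")
  for (i in seq_len(nrow(tr))) {
    reg <- panel$target_seq[key == paste(sim$truth$species[i],
                                         sim$truth$pair[i], sep = "|")]
    q <- if (sim$truth$strand[i] == "-") revcomp(tr$sequence[i])
         else tr$sequence[i]
    al <- glocal_align(q, reg)
    expect_equal(al$n_mismatch, sim$truth$n_sub[i])
    expect_equal(al$n_ins + al$n_del, 0L)
  }

  # homopolymer indels only: recoverable except when events in adjacent
  # runs cancel into a cheaper substitution, which the aligner is right to
  # prefer; exclude exactly those reads
  hpmod <- error_model(sub_rate = 0,
                       hp_indel_rate = function(L) pmin(0.05 * (L - 1), 0.3))
  sim2 <- simulate_library(pool, panel, err = hpmod, n_reads = 150,
                           seed = 52)
  tr2 <- trim_primers(sim2$reads, meat_primer_pairs())
  checked <- 0L
  for (i in seq_len(nrow(tr2))) {
    tru <- sim2$truth[i, ]
    if (tru$n_ins + tru$n_del != 1L) next  # single events cannot cancel
    reg <- panel$target_seq[key == paste(tru$species, tru$pair, sep = "|")]
    q <- if (tru$strand == "-") revcomp(tr2$sequence[i]) else tr2$sequence[i]
    # a deletion in the first or last run of the target is absorbed by the
    # aligner's free reference ends (a shorter clean alignment scores
    # higher than one paying a terminal gap) - inherent to glocal
    # alignment, so exclude exactly that case
    if (tru$n_del == 1L &&
        (q == substr(reg, 2L, nchar(reg)) ||
         q == substr(reg, 1L, nchar(reg) - 1L))) next
    al <- glocal_align(q, reg)
    expect_equal(al$n_ins, tru$n_ins)
    expect_equal(al$n_del, tru$n_del)
    expect_equal(al$n_mismatch, 0L)
    checked <- checked + 1L
  }
  expect_gt(checked, 10L)
})
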