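test_that("counting increments cells and conserves reads", {
  asg <- data.frame(
    species = c(rep("pig", 3), rep("horse", 2)),
    pair = c(rep("12S_KH", 3), rep("16S_Ki", 2)),
    stringsAsFactors = FALSE)
  ct <- count_by_region(asg, "demo", unassigned = 4L)
  expect_equal(ct$count[ct$species == "pig"], 3L)
  expect_equal(ct$count[ct$species == "horse"], 2L)
  expect_equal(sum(ct$count), 5L)
  expect_equal(attr(ct, "unassigned"), 4L)
})

test_that("bundled dilution-series counts reproduce the published totals", {
  ds <- dilution_series_counts()
  expect_equal(unname(pair_totals(ds$lib4)["16S_Ki"]), 16639)
  expect_equal(unname(pair_totals(ds$lib5)["12S_KH"]), 4917)
  expect_equal(sum(ds$lib4$count), 5261 + 3110 + 16639)
})

test_that("counts reconcile with the simulation truth table", {
  panel <- fixture_panel()
  pool <- pool_spec("mix", setNames(rep(100, 3), unique(panel$species)))
  sim <- simulate_library(pool, panel, n_reads = 400, seed = 71)
  tr <- trim_primers(sim$reads, meat_primer_pairs())
  flt <- filter_alignments(map_reads(tr, panel))
  ct <- count_by_region(flt$retained, "sim", panel = panel,
                        unassigned = 400L - nrow(flt$retained))
  expect_equal(sum(ct$count) + attr(ct, "unassigned"), 400L)
  # read-by-read: retained assignments match the truth
  m <- match(flt$retained$read_id, sim$truth$read_id)
  tru_key <- paste(sim$truth$species[m], sim$truth$pair[m])
  expect_equal(paste(flt$retained$species, flt$retained$pair), tru_key)
  tru_ct <- table(tru_key)
  got <- setNames(ct$count, paste(ct$species, ct$pair))
  expect_equal(got[names(tru_ct)], as.table(tru_ct), ignore_attr = TRUE)
})

test_that("species aggregation yields within-pair proportions", {
  ct <- count_table(data.frame(
    species = c("A", "B", "A", "B"), pair = c("p1", "p1", "p2", "p2"),
    count = c(80L, 20L, 0L, 0L), stringsAsFactors = FALSE))
  agg <- aggregate_by_species(ct)
  expect_equal(agg$proportions$prop[1:2], c(0.8, 0.2))
  expect_true(all(is.na(agg$proportions$prop[3:4])))  # all-zero pair

  # class grouping equals brute-force summation over an explicit map
  ds <- dilution_series_counts()
  cls <- c(pig = "white", horse = "red", cattle = "red", sheep = "red",
           rabbit = "white", human = "other", rat = "other")
  agg4 <- aggregate_by_species(ds$lib4, classes = cls)
  for (p in unique(ds$lib4$pair)) for (g in unique(cls)) {
    manual <- sum(ds$lib4$count[ds$lib4$pair == p &
                                cls[ds$lib4$species] == g])
    expect_equal(agg4$class_proportions[g, p],
                 manual / sum(ds$lib4$count[ds$lib4$pair == p]))
  }
  expect_equal(colSums(agg4$class_proportions), c(`12S_KH` = 1,
                                                  `16S_KH` = 1,
                                                  `16S_Ki` = 1))
})

test_that("per-ng normalization matches the pool arithmetic", {
  ct <- count_table(data.frame(species = "pig", pair = "12S_KH",
                               count = 100L, stringsAsFactors = FALSE))
  pool2 <- pool_spec("p", c(pig = 20, cattle = 180), reaction_ng = 20)
  nm <- normalize_per_ng(ct, pool2)   # pig gets 2 ng per reaction
  expect_equal(nm$reaction_ng, 2)
  expect_equal(nm$reads_per_ng, 50)

  # scale equivariance: doubling counts doubles normalized values
  ct2 <- count_table(transform(as.data.frame(ct), count = count * 2L))
  expect_equal(normalize_per_ng(ct2, pool2)$reads_per_ng, 100)

  expect_error(normalize_per_ng(ct, pool_spec("q", c(cattle = 1))), "pig")
})

test_that("error rates estimate the simulated substitution rate", {
  # forced arithmetic: one deleted base over 100 aligned reference bases
  one <- data.frame(species = "pig", pair = "12S_KH", n_mismatch = 0L,
                    n_ins = 0L, n_del = 1L, aligned_ref_bases = 100L,
                    stringsAsFactors = FALSE)
  et <- estimate_error_rates(one)
  expect_equal(et$rate, 0.01)
  expect_equal(estimate_error_rates(one, include_indels = FALSE)$rate, 0)

  # error-free library: all rates zero
  panel <- fixture_panel()
  pool <- pool_spec("mix", setNames(rep(100, 3), unique(panel$species)))
  clean <- error_model(sub_rate = 0,
                       hp_indel_rate = function(L) rep(0, length(L)))
  sim <- simulate_library(pool, panel, err = clean, n_reads = 150, seed = 81)
  tr <- trim_primers(sim$reads, meat_primer_pairs())
  flt <- filter_alignments(map_reads(tr, panel))
  expect_true(all(estimate_error_rates(flt$retained)$rate == 0))

  # parameter recovery: sub_rate 0.005 over >= 50k aligned bases
  submod <- error_model(sub_rate = 0.005,
                        hp_indel_rate = function(L) rep(0, length(L)))
  sim2 <- simulate_library(pool, panel, err = submod, n_reads = 500,
                           seed = 82)
  tr2 <- trim_primers(sim2$reads, meat_primer_pairs())
  flt2 <- filter_alignments(map_reads(tr2, panel))
  et2 <- estimate_error_rates(flt2$retained)
  bases <- sum(et2$aligned_ref_bases)
  expect_gte(bases, 50000)
  pooled <- sum(et2$mismatch_bases) / bases
  ci <- qnorm(0.995) * sqrt(0.005 * 0.995 / bases)
  expect_lt(abs(pooled - 0.005), ci)

  # invariance to read order
  shuf <- flt2$retained[sample(nrow(flt2$retained)), ]
  expect_equal(estimate_error_rates(shuf)$rate, et2$rate)
})

test_that("pearson correlation handles exact and degenerate cases", {
  x <- c(1, 5, 9, 13)
  expect_equal(pearson_correlation(x, 2 * x), 1)
  expect_equal(pearson_correlation(x, -x + 20), -1)
  expect_warning(r <- pearson_correlation(x, rep(3, 4)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_correlation(1:2, 1:2), "length >= 3")
})

test_that("species detection follows the read/pair thresholds", {
  ds <- dilution_series_counts()
  # horse in the 1:50 library: counts (1, 0, 17) across the three pairs
  calls <- call_species(ds$lib5, min_reads = 1, min_pairs = 2)
  horse <- calls[calls$species == "horse", ]
  expect_true(horse$detected)
  expect_setequal(strsplit(horse$supporting_pairs, ",")[[1]],
                  c("12S_KH", "16S_Ki"))
  # absent species are reported undetected, not dropped
  calls2 <- call_species(ds$lib5, species = c(unique(ds$lib5$species),
                                              "goat"))
  expect_false(calls2$detected[calls2$species == "goat"])
  expect_equal(calls2$total_reads[calls2$species == "goat"], 0)

  # detection of a diluted species is monotone non-increasing in min_reads
  panel13 <- suppressWarnings(
    build_panel(synthetic_references(seed = 11), meat_primer_pairs()))
  sim <- simulate_library(meat_pools()$e, panel13, n_reads = 8000, seed = 83)
  ct <- count_by_region(sim$truth, "truth", panel = panel13)
  det <- vapply(1:50, function(k)
    call_species(ct, min_reads = k)$detected[
      call_species(ct, min_reads = k)$species == "pig"], logical(1))
  expect_true(all(diff(as.integer(det)) <= 0))
})

test_that("library comparison slices correlate and flag degeneracy", {
  ds <- dilution_series_counts()
  self <- compare_libraries(list(ds$lib4, ds$lib4))
  expect_true(all(self$r[!self$degenerate] == 1))

  both <- compare_libraries(list(ds$lib4, ds$lib5),
                            classes = c(pig = "mammal", horse = "mammal",
                                        cattle = "mammal", sheep = "mammal",
                                        rabbit = "mammal", human = "mammal",
                                        rat = "mammal"))
  expect_gt(both$r[both$slice == "all"], 0.98)
  expect_equal(both$n[both$slice == "all"], 21L)

  # an all-zero slice in one library must be flagged, never reported as 1
  za <- count_table(data.frame(species = rep(c("chicken", "duck", "goose"), 2),
                               pair = rep(c("p1", "p2"), each = 3),
                               count = 0L, stringsAsFactors = FALSE), "za")
  zb <- count_table(data.frame(species = rep(c("chicken", "duck", "goose"), 2),
                               pair = rep(c("p1", "p2"), each = 3),
                               count = c(5L, 8L, 2L, 1L, 9L, 4L),
                               stringsAsFactors = FALSE), "zb")
  cmp <- compare_libraries(list(za, zb),
                           classes = c(chicken = "avian", duck = "avian",
                                       goose = "avian"))
  expect_true(all(cmp$degenerate))
  expect_true(all(is.na(cmp$r)))

  expect_error(compare_libraries(list(za)), ">= 2")
})
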