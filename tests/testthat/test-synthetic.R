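lay1 <- genome_layout("chrT", 2e6)

test_that("simulated genomes are reproducible with near-uniform composition", {
  small <- genome_layout("chrS", 1000)
  g1 <- simulate_genome(small, seed = 1)
  g2 <- simulate_genome(small, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(nchar(as.character(g1)[["chrS"]]), 1000L)
  expect_true(all(strsplit(as.character(g1)[[1]], "")[[1]] %in%
                    c("A", "C", "G", "T")))

  big <- simulate_genome(genome_layout("chrM", 1e6), seed = 2)
  freq <- table(strsplit(as.character(big)[[1]], "")[[1]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("event-free clone pairs are almost all concordant under mean±4sd bounds", {
  cp <- simulate_clone_pairs(truth_set(), lay1, 1000, 39000, 1000, 500,
                             seed = 21)
  b <- concordance_bounds(39000 - 4000, 39000 + 4000)
  cls <- classify_pairs(cp$pairs, b)
  expect_gte(mean(cls == "concordant"), 0.99)
  # determinism
  cp2 <- simulate_clone_pairs(truth_set(), lay1, 1000, 39000, 1000, 500,
                              seed = 21)
  expect_identical(cp$pairs, cp2$pairs)
})

test_that("fragments spanning a large tandem-duplication junction are everted", {
  # unit (200 kb) much longer than the insert: a junction-spanning fragment
  # must have both ends inside duplicated copies, forcing eversion
  tr <- truth_set(duplications = data.frame(
    chrom = "chrT", start = 1e6, end = 1.2e6,
    copies_hap1 = 2, copies_hap2 = 2))
  cp <- simulate_clone_pairs(tr, genome_layout("chrT", 3e6), 5000,
                             39000, 1000, 500, seed = 22)
  cls <- classify_pairs(cp$pairs)
  spans <- cp$clones$spans_dup_junction[match(cp$pairs$clone_id,
                                              cp$clones$clone_id)]
  expect_gt(sum(spans), 20)
  expect_true(all(cls[spans] == "everted"))
  # and eversion arises only at junctions (no events elsewhere)
  expect_true(all(spans[cls == "everted"]))
})

test_that("window depth follows the copy-number scaled Poisson law", {
  lay <- genome_layout("chrD", 6e6)
  # CN 2 everywhere: mean rate = mean_diploid_depth within 3 s.e.
  d0 <- simulate_depth(truth_set(), lay, mean_diploid_depth = 30, seed = 31)
  rate <- d0$depth / d0$unmasked_bp
  se <- sqrt(30 / mean(d0$unmasked_bp) / nrow(d0))
  expect_lt(abs(mean(rate) - 30), 3 * se)
  expect_true(all(d0$depth >= 0))

  # homozygous CN 4 region: ratio to background ~ 2.0
  tr <- truth_set(duplications = data.frame(
    chrom = "chrD", start = 2e6, end = 3e6, copies_hap1 = 2, copies_hap2 = 2))
  d1 <- simulate_depth(tr, lay, mean_diploid_depth = 30, seed = 32)
  inside <- d1$start >= 2e6 & d1$end <= 3e6
  outside <- d1$end <= 2e6 | d1$start >= 3e6
  ratio <- mean(d1$depth[inside] / d1$unmasked_bp[inside]) /
    mean(d1$depth[outside] / d1$unmasked_bp[outside])
  expect_lt(abs(ratio - 2), 0.05)
  # determinism
  d2 <- simulate_depth(tr, lay, mean_diploid_depth = 30, seed = 32)
  expect_identical(d1, d2)
})

test_that("finished clones carry exactly the recorded errors", {
  g <- simulate_genome(genome_layout(c("c1", "c2"), c(60000, 40000)),
                       seed = 41)
  # zero rates: exact substrings
  fc0 <- simulate_finished_clones(g, 5, 10000, 0, 0, seed = 42)
  seqs <- as.character(g)
  for (i in 1:5) {
    t <- fc0$truth[i, ]
    expect_identical(as.character(fc0$clones)[[t$clone_id]],
                     substr(seqs[[t$chrom]], t$start + 1, t$end))
  }
  expect_true(all(fc0$truth$n_sub == 0 & fc0$truth$n_ins == 0 &
                    fc0$truth$n_del == 0))

  # substitutions only: truth counts equal an independent string diff
  fc1 <- simulate_finished_clones(g, 5, 10000, 1e-3, 0, seed = 43)
  for (i in 1:5) {
    t <- fc1$truth[i, ]
    d <- oracle_string_diff(as.character(fc1$clones)[[t$clone_id]],
                            substr(seqs[[t$chrom]], t$start + 1, t$end))
    expect_equal(d, t$n_sub)
  }
  # binomial scale: ~40 subs per 40 kb at 1e-3
  fc2 <- simulate_finished_clones(g, 20, 40000, 1e-3, 0, seed = 44)
  expect_lt(abs(mean(fc2$truth$n_sub) - 40), 3 * sqrt(40 / 20))

  # indels change clone length by ins - del
  fc3 <- simulate_finished_clones(g, 5, 10000, 0, 1e-3, seed = 45)
  expect_equal(nchar(as.character(fc3$clones)),
               10000 + fc3$truth$n_ins - fc3$truth$n_del,
               ignore_attr = TRUE)
})

test_that("split-read simulation hits the unit boundaries", {
  s0 <- simulate_split_reads("chr6", 49729008, 49743863, 8, seed = 51)
  expect_true(all(s0$seg1_end == 49743863))
  expect_true(all(s0$seg2_start == 49729008))
  expect_equal(nrow(simulate_split_reads("c", 10, 20, 0)), 0L)

  sj <- simulate_split_reads("chr6", 49729008, 49743863, 31, jitter = 50,
                             seed = 52)
  expect_lte(abs(median(sj$seg1_end) - 49743863), 50)
  expect_lte(abs(median(sj$seg2_start) - 49729008), 50)
})

test_that("truth-set validation enforces its invariants", {
  expect_error(truth_set(sub_rate = 1), "rates")
  expect_error(truth_set(duplications = data.frame(
    chrom = "c", start = 0, end = 10, copies_hap1 = 0, copies_hap2 = 1)),
    "copy counts")
  expect_error(truth_set(misassemblies = data.frame(
    chrom = "c", start = 0, end = 10, kind = "swap")), "kind")
  # event beyond layout detected at simulation time
  tr <- truth_set(duplications = data.frame(
    chrom = "chrT", start = 0, end = 3e6, copies_hap1 = 2, copies_hap2 = 1))
  expect_error(simulate_clone_pairs(tr, lay1, 10, 39000, 1000, 500, seed = 1),
               "beyond")
})
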