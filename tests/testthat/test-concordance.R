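mkpair <- function(pos_a, strand_a, pos_b, strand_b, chrom_a = "chr1",
                   chrom_b = chrom_a, read_len = 500) {
  data.frame(clone_id = "c", chrom_a = chrom_a, pos_a = pos_a,
             strand_a = strand_a, chrom_b = chrom_b, pos_b = pos_b,
             strand_b = strand_b, read_len = read_len,
             stringsAsFactors = FALSE)
}

test_that("implied fragments follow the min/max + read_len definition", {
  f <- implied_fragment(mkpair(100000, "+", 139000, "-"))
  expect_equal(c(f$start, f$end, f$size), c(100000, 139500, 39500))
  # degenerate equal positions: size = read_len
  f2 <- implied_fragment(mkpair(5000, "+", 5000, "-"))
  expect_equal(f2$size, 500)
  # interchromosomal: undefined
  f3 <- implied_fragment(mkpair(100, "+", 200, "-", chrom_b = "chr2"))
  expect_true(is.na(f3$chrom) && is.na(f3$size))
})

test_that("pair classification matches the orientation/size rules", {
  b <- concordance_bounds()  # 35,328 - 43,453
  expect_equal(as.character(classify_pairs(mkpair(100000, "+", 139000, "-"), b)),
               "concordant")                                # size 39,500
  expect_equal(as.character(classify_pairs(mkpair(100000, "+", 143500, "-"), b)),
               "discordant_size_long")                      # size 44,000
  expect_equal(as.character(classify_pairs(mkpair(100000, "-", 139000, "+"), b)),
               "everted")        # leftmost read on minus strand
  expect_equal(as.character(classify_pairs(mkpair(100000, "+", 139000, "+"), b)),
               "same_strand")
  expect_equal(as.character(classify_pairs(
    mkpair(100, "+", 200, "-", chrom_b = "chr2"), b)), "interchromosomal")
  # inclusive bounds on both ends
  expect_equal(as.character(classify_pairs(mkpair(0, "+", 34828, "-"), b)),
               "concordant")                                # size exactly 35,328
  expect_equal(as.character(classify_pairs(mkpair(0, "+", 42953, "-"), b)),
               "concordant")                                # size exactly 43,453
  expect_equal(as.character(classify_pairs(mkpair(0, "+", 42954, "-"), b)),
               "discordant_size_long")
})

test_that("classification is total and the classes partition random pairs", {
  set.seed(61)
  n <- 500
  p <- data.frame(clone_id = paste0("c", 1:n),
                  chrom_a = sample(c("c1", "c2"), n, TRUE),
                  pos_a = sample.int(1e6, n),
                  strand_a = sample(c("+", "-"), n, TRUE),
                  chrom_b = sample(c("c1", "c2"), n, TRUE),
                  pos_b = sample.int(1e6, n),
                  strand_b = sample(c("+", "-"), n, TRUE),
                  read_len = 500, stringsAsFactors = FALSE)
  cls <- classify_pairs(p)
  expect_false(anyNA(cls))
  expect_equal(length(cls), n)
  expect_true(all(levels(cls) == c("concordant", "discordant_size_short",
                                   "discordant_size_long", "everted",
                                   "same_strand", "interchromosomal")))
})

test_that("physical coverage equals the brute-force window recount", {
  layout <- genome_layout("chrT", 20000)
  # no fragments -> all-zero track
  t0 <- physical_coverage(genomic_intervals("chrT", 1, 2)[0, ], layout,
                          window = 5000)
  expect_equal(t0$count, rep(0, 4))
  # boundary-straddling fragment hits windows 0 and 1 only
  t1 <- physical_coverage(genomic_intervals("chrT", 4999, 5001), layout,
                          window = 5000)
  expect_equal(t1$count, c(1, 1, 0, 0))

  # random fragments vs oracle, plus count conservation
  layout2 <- genome_layout(c("cA", "cB"), c(104000, 52000))  # partial windows
  set.seed(62)
  fr <- rand_intervals(500, layout2, max_len = 20000)
  track <- physical_coverage(fr, layout2, window = 5000)
  expect_equal(track, oracle_coverage(fr, layout2, 5000),
               ignore_attr = TRUE)
  # sum of counts = sum over fragments of windows overlapped
  per_frag <- floor((fr$end - 1) / 5000) - floor(fr$start / 5000) + 1
  expect_equal(sum(track$count), sum(per_frag))
  # fragment on unknown chromosome errors
  expect_error(physical_coverage(genomic_intervals("nope", 0, 10), layout),
               "absent")
})

test_that("unsupported intervals are zero runs with chromosome ends discarded", {
  layout <- genome_layout("chrT", 20000)
  # all-zero chromosome: the single run touches both ends -> nothing
  t0 <- physical_coverage(genomic_intervals("chrT", 1, 2)[0, ], layout, 5000)
  expect_equal(nrow(unsupported_intervals(t0, layout)), 0L)
  # counts [1,0,0,1] -> one interval over windows 1-2
  tr <- data.frame(chrom = "chrT", start = c(0, 5000, 10000, 15000),
                   end = c(5000, 10000, 15000, 20000), count = c(1, 0, 0, 1))
  u <- unsupported_intervals(tr, layout)
  expect_equal(u, data.frame(chrom = "chrT", start = 5000, end = 15000),
               ignore_attr = TRUE)

  # random tracks vs oracle
  set.seed(63)
  layout2 <- genome_layout(c("cA", "cB"), c(100000, 60000))
  for (rep in 1:10) {
    fr <- rand_intervals(30, layout2, max_len = 15000)
    track <- physical_coverage(fr, layout2, window = 5000)
    expect_equal(unsupported_intervals(track, layout2),
                 oracle_unsupported(track, layout2), ignore_attr = TRUE)
  }
})

test_that("adding a concordant fragment never increases unsupported length", {
  layout <- genome_layout("chrT", 200000)
  set.seed(64)
  fr <- rand_intervals(15, layout, max_len = 40000)
  base <- interval_footprint_bp(unsupported_intervals(
    physical_coverage(fr, layout, 5000), layout))
  for (rep in 1:10) {
    fr2 <- rbind(fr, rand_intervals(1, layout, max_len = 40000))
    newlen <- interval_footprint_bp(unsupported_intervals(
      physical_coverage(fr2, layout, 5000), layout))
    expect_lte(newlen, base)
  }
})

test_that("spurious assembly sequence is recovered by the zero-coverage screen", {
  # 20 kb of assembly sequence with no counterpart in the sample: every
  # window fully inside it has zero concordant physical coverage
  lay <- genome_layout("chrT", 2e6)
  tr <- truth_set(misassemblies = data.frame(
    chrom = "chrT", start = 1e6, end = 1.02e6, kind = "insertion"))
  cp <- simulate_clone_pairs(tr, lay, 2000, 39000, 1000, 500, seed = 65)
  scr <- concordance_screen(cp$pairs, lay, concordance_bounds(35000, 43000))
  expect_gte(nrow(scr$unsupported), 1L)
  expect_true(any(scr$unsupported$start < 1.02e6 &
                    scr$unsupported$end > 1e6))
})

test_that("inversion breakpoints produce a same-strand discordance signature", {
  # an inversion preserves fragment sizes, so pairs spanning the whole
  # segment (and pairs inside it) stay concordant; the detectable signal is
  # same-strand pairs with exactly one end inside the inverted segment
  lay <- genome_layout("chrT", 2e6)
  s <- 1e6; e <- 1.015e6
  tr <- truth_set(misassemblies = data.frame(
    chrom = "chrT", start = s, end = e, kind = "inversion"))
  cp <- simulate_clone_pairs(tr, lay, 2000, 39000, 1000, 500, seed = 66)
  cls <- classify_pairs(cp$pairs, concordance_bounds(35000, 43000))
  frag <- implied_fragment(cp$pairs)
  ss <- which(cls == "same_strand")
  expect_gt(length(ss), 5)
  # all same-strand pairs localise to the breakpoints (within one insert)
  expect_true(all(frag$end[ss] > s - 45000 & frag$start[ss] < e + 45000))
})
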