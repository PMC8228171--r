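test_that("CN windows accumulate exactly the target unmasked content", {
  lay <- genome_layout("c1", 9000)
  # no mask: three 3 kb windows
  w0 <- make_cn_windows(lay, unmasked_target = 3000)
  expect_equal(w0$start, c(0, 3000, 6000))
  expect_equal(w0$end, c(3000, 6000, 9000))
  expect_equal(w0$unmasked_bp, rep(3000, 3))
  # mask over the first 3 kb: first window stretches to 6 kb
  w1 <- make_cn_windows(lay, mask = genomic_intervals("c1", 0, 3000),
                        unmasked_target = 3000)
  expect_equal(w1$start[1], 0)
  expect_equal(w1$end[1], 6000)
  expect_equal(w1$unmasked_bp[1], 3000)

  # random masks: brute-force per-bp recount of unmasked content per window
  set.seed(91)
  lay2 <- genome_layout("c2", 50000)
  mask <- merge_intervals(rand_intervals(20, lay2, max_len = 3000))
  w <- make_cn_windows(lay2, mask = mask, unmasked_target = 2000)
  masked_bp <- rep(FALSE, 50000)
  for (i in seq_len(nrow(mask)))
    masked_bp[(mask$start[i] + 1):mask$end[i]] <- TRUE
  recount <- vapply(seq_len(nrow(w)), function(k)
    sum(!masked_bp[(w$start[k] + 1):w$end[k]]), 0)
  expect_equal(w$unmasked_bp, recount)
  expect_true(all(w$unmasked_bp[-nrow(w)] == 2000))
  # non-overlapping, sorted, conserving total unmasked bp
  expect_true(all(w$start[-1] == w$end[-nrow(w)]))
  expect_equal(sum(w$unmasked_bp), sum(!masked_bp))
})

test_that("copy-number estimation is a normalization identity and scale-invariant", {
  d <- data.frame(chrom = "c1", start = seq(0, 27000, 3000),
                  end = seq(3000, 30000, 3000), unmasked_bp = 3000,
                  depth = c(rep(90000, 5), 270000, rep(90000, 4)))
  controls <- genomic_intervals("c1", 0, 15000)
  cn <- estimate_copy_number(d, controls)
  expect_equal(cn$cn[1:5], rep(2, 5))       # control rate -> CN 2
  expect_equal(cn$cn[6], 6)                 # 3x control -> CN 6
  # scale invariance
  d2 <- d; d2$depth <- d2$depth * 7
  expect_equal(estimate_copy_number(d2, controls)$cn, cn$cn)
  # zero control depth errors
  d3 <- d; d3$depth[1:5] <- 0
  expect_error(estimate_copy_number(d3, genomic_intervals("c1", 0, 15000)),
               "control")
})

test_that("duplication calling applies the 4-window / CN 2.5 run rule", {
  mkwin <- function(cn) {
    n <- length(cn)
    structure(data.frame(chrom = "c1", start = seq(0, by = 3000, length.out = n),
                         end = seq(3000, by = 3000, length.out = n),
                         unmasked_bp = 3000, depth = 1, cn = cn),
              unmasked_target = 3000)
  }
  # run of 3 at CN 3: below min_run -> no call
  expect_equal(nrow(call_duplications(mkwin(c(3, 3, 3)))), 0L)
  # [2, 3, 3, 2.5, 2.6, 1]: windows 1-4 qualify (inclusive 2.5)
  calls <- call_duplications(mkwin(c(2, 3, 3, 2.5, 2.6, 1)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 3000)
  expect_equal(calls$end, 15000)
  expect_equal(calls$n_windows, 4L)

  # random CN vectors vs run-scanner oracle
  set.seed(92)
  for (rep in 1:15) {
    cn <- round(runif(40, 0, 5), 2)
    got <- call_duplications(mkwin(cn))
    want <- oracle_dup_calls(mkwin(cn), 4, 2.5, function(w) rep(TRUE, nrow(w)))
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("self-alignment duplication filter applies inclusive thresholds", {
  rec <- data.frame(
    chrom1 = c("c1", "c1", "c2"), start1 = c(0, 1000, 0),
    end1 = c(5000, 2000, 1000),
    chrom2 = c("c1", "c2", "c2"), start2 = c(10000, 500, 4000),
    end2 = c(15000, 1500, 5000),
    identity = c(89.9, 95, 92), length = c(5000, 1000, 999))
  f <- filter_self_alignment_dups(rec)
  expect_equal(nrow(f$retained), 1L)      # 89.9 dropped, 999 bp dropped
  expect_equal(f$retained$identity, 95)
  # footprint is the union of both intervals of retained records
  expect_equal(f$footprint,
               data.frame(chrom = c("c1", "c2"), start = c(1000, 500),
                          end = c(2000, 1500)), ignore_attr = TRUE)

  # random tables: footprint equals a brute-force per-bp union
  set.seed(93)
  lay <- genome_layout("cZ", 20000)
  r1 <- rand_intervals(10, lay, 2000); r2 <- rand_intervals(10, lay, 2000)
  rec2 <- data.frame(chrom1 = r1$chrom, start1 = r1$start, end1 = r1$end,
                     chrom2 = r2$chrom, start2 = r2$start, end2 = r2$end,
                     identity = runif(10, 80, 100),
                     length = sample.int(3000, 10))
  f2 <- filter_self_alignment_dups(rec2)
  keep <- rec2$identity >= 90 & rec2$length >= 1000
  covered <- rep(FALSE, 20000)
  for (i in which(keep)) {
    covered[(rec2$start1[i] + 1):rec2$end1[i]] <- TRUE
    covered[(rec2$start2[i] + 1):rec2$end2[i]] <- TRUE
  }
  expect_equal(interval_footprint_bp(f2$footprint), sum(covered))
})

test_that("an engineered homozygous duplication is recovered by depth CN calling", {
  # CN 4 over 6+ windows at 30x: recovered with >= 80% reciprocal overlap
  lay <- genome_layout("cR", 3e6)
  tr <- truth_set(duplications = data.frame(
    chrom = "cR", start = 1.5e6, end = 1.52e6,   # ~6.7 windows
    copies_hap1 = 2, copies_hap2 = 2))
  ok <- vapply(1:20, function(i) {
    dep <- simulate_depth(tr, lay, mean_diploid_depth = 30, seed = 9300 + i)
    cn <- estimate_copy_number(dep, genomic_intervals(
      "cR", c(0, 1.6e6), c(1.4e6, 3e6)))
    calls <- call_duplications(cn)
    if (nrow(calls) == 0L) return(FALSE)
    ov <- pmin(calls$end, 1.52e6) - pmax(calls$start, 1.5e6)
    any(ov >= 0.8 * 2e4 & ov >= 0.8 * (calls$end - calls$start))
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("a 12-copy diploid tandem array yields median CN near 12", {
  lay <- genome_layout("cA", 5e6)
  tr <- truth_set(duplications = data.frame(
    chrom = "cA", start = 2e6, end = 2015000,
    copies_hap1 = 6, copies_hap2 = 6))
  dep <- simulate_depth(tr, lay, mean_diploid_depth = 30, seed = 94)
  cn <- estimate_copy_number(dep, genomic_intervals(
    "cA", c(0, 2.1e6), c(1.9e6, 5e6)))
  arr <- cn$start >= 2e6 & cn$end <= 2015000
  expect_lte(abs(median(cn$cn[arr]) - 12), 0.5)
})
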