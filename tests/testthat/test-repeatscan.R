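test_that("dispersed_repeats: clean genome, planted duplication, tandem ladder", {
  # random genome: nothing at 1e-6 / >=30 bp; SW oracle agrees on a subsample
  g <- genome("clean", rand_seq(5000, seed = 61))
  h <- dispersed_repeats(g)
  expect_identical(nrow(h), 0L)
  sub1 <- substr(g$sequence, 1, 1000); sub2 <- substr(g$sequence, 2001, 3000)
  ka <- solve_karlin_altschul(scoring_scheme())
  expect_lt(local_align(sub1, sub2)$score,
            evalue_score_threshold(1e-6, ka, 1000, 1000))

  # planted exact 2 kb duplication: one reciprocal off-diagonal pair
  bg <- rand_seq(6000, seed = 62)
  seg <- rand_seq(2000, seed = 63)
  gd <- genome("dup", insert_at(insert_at(bg, 1000, seg), 5000, seg))
  hd <- dispersed_repeats(gd)
  hd <- hd[hd$strand == "+", ]
  expect_identical(nrow(hd), 2L)
  expect_true(all(hd$length >= 2000))

  # perfect 3x tandem of a 500 bp motif: self-lags at 500 and 1000
  motif <- rand_seq(500, seed = 64)
  gt <- genome("tan", strrep(motif, 3))
  ht <- dispersed_repeats(gt)
  lags <- unique(abs(ht$qstart - ht$sstart)[ht$strand == "+"])
  expect_setequal(lags, c(500L, 1000L))
})

test_that("tandem_repeats: pure array, planted array, random null", {
  tr <- tandem_repeats(genome("t", strrep("ACGT", 50)))
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$period, 4L)
  expect_equal(tr$copy_number, 50, tolerance = 0.5)

  # period 51 x 4 copies planted in random background
  motif <- rand_seq(51, seed = 71)
  gp <- genome("p", insert_at(rand_seq(4000, seed = 72), 1500,
                              strrep(motif, 4)))
  trp <- tandem_repeats(gp)
  expect_identical(nrow(trp), 1L)
  expect_identical(trp$period, 51L)
  expect_equal(trp$copy_number, 4, tolerance = 0.5)
  expect_gte(trp$start, 1400); expect_lte(trp$end, 1810)

  # 10 kb random sequence: no array reaches score 50
  expect_identical(nrow(tandem_repeats(genome("r", rand_seq(10000, seed = 73)))),
                   0L)
})

test_that("partition_repeats: percentages, bins, conservation", {
  g <- genome("clean", rand_seq(4000, seed = 81))
  ct <- partition_repeats(g)
  expect_equal(ct$single_copy_pct, 100)
  expect_identical(ct$repetitive_bp, 0L)

  # 10 kb genome with a 2 kb duplication (two copies)
  bg <- rand_seq(6000, seed = 82)
  seg <- rand_seq(2000, seed = 83)
  gd <- genome("dup", insert_at(insert_at(bg, 1000, seg), 5000, seg))
  cd <- partition_repeats(gd)
  expect_equal(cd$repetitive_bp, 4000, tolerance = 14 / 4000) # 2*word slack
  expect_equal(cd$single_copy_pct, 60, tolerance = 0.5)
  expect_identical(as.integer(cd$bin_counts[">1000"]), 2L)
  # conservation holds exactly
  expect_identical(cd$repetitive_bp + cd$single_copy_bp, cd$genome_length)
  expect_equal(cd$repetitive_pct + cd$single_copy_pct, 100)
  # merged units are pairwise disjoint
  mu <- cd$merged_units
  if (nrow(mu) > 1) expect_true(all(mu$start[-1] > mu$end[-nrow(mu)]))
})

test_that("repetitive_bp is monotone in evalue_max and min_repeat_len", {
  cfg <- simulation_config(seed = 91)
  g <- evolve(cfg)$genomes$A
  base <- partition_repeats(g, repeat_params())
  loose_e <- partition_repeats(g, repeat_params(evalue_max = 1e-3))
  short_l <- partition_repeats(g, repeat_params(min_repeat_len = 20L))
  expect_gte(loose_e$repetitive_bp, base$repetitive_bp)
  expect_gte(short_l$repetitive_bp, base$repetitive_bp)
})

test_that("collapse_large_repeats deletes all but one copy and is idempotent", {
  # no >1 kb repeat: a no-op
  g <- genome("clean", rand_seq(4000, seed = 92))
  c0 <- collapse_large_repeats(g)
  expect_identical(c0$collapsed_len_bp, 4000L)

  # 20 kb genome with one 2 kb segment at three positions
  bg <- rand_seq(14000, seed = 93)
  seg <- rand_seq(2000, seed = 94)
  g3 <- genome("x3", insert_at(insert_at(insert_at(bg, 2000, seg),
                                         9000, seg), 13000, seg))
  expect_identical(g3$length_bp, 20000L)
  c3 <- collapse_large_repeats(g3)
  expect_equal(c3$collapsed_len_bp, 20000 - 2 * 2000, tolerance = 30 / 16000)
  # leftmost copy retained: the first planted copy survives
  expect_gt(regexpr(substr(seg, 101, 300), c3$sequence, fixed = TRUE)[1], 0)

  # idempotent: collapsing a collapsed genome changes nothing
  c3b <- collapse_large_repeats(c3)
  expect_identical(c3b$collapsed_len_bp, c3$collapsed_len_bp)
  expect_identical(c3b$sequence, c3$sequence)
})
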