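test_that("shared_dna: self-comparison and simulator truth recovery", {
  g <- genome("g", rand_seq(8000, seed = 101))
  expect_equal(shared_dna(g, g)$shared_pct, 100)

  # two leaves, ~40% of IGS replaced independently per lineage, genes kept
  bl <- -log(0.6) / 100 # turnover 100 => 40% replaced per branch
  cfg <- simulation_config(tree = sprintf("(A:%.6f,B:%.6f);", bl, bl),
                           repeat_events = list(), mipt_events = list(),
                           seed = 102)
  sim <- evolve(cfg)
  sd <- shared_dna(sim$genomes$A, sim$genomes$B)
  truth_pct <- 100 * sim$truth$shared_frac["A", "B"]
  expect_equal(sd$shared_pct, truth_pct, tolerance = 5 / truth_pct)
})

test_that("adding unrelated sequence obeys coverage monotonicity", {
  cfg <- simulation_config(tree = "(A:0.003,B:0.003);",
                           repeat_events = list(), mipt_events = list(),
                           seed = 103)
  sim <- evolve(cfg)
  q <- sim$genomes$A; s <- sim$genomes$B
  base <- shared_dna(q, s)
  s_plus <- genome("Bplus", paste0(s$sequence, rand_seq(10000, seed = 104)))
  q_plus <- genome("Aplus", paste0(q$sequence, rand_seq(10000, seed = 105)))
  expect_gte(shared_dna(q, s_plus)$shared_bp, base$shared_bp)
  expect_lte(shared_dna(q_plus, s)$shared_pct, base$shared_pct)
})

test_that("mipt_scan: null pair, planted insertions, length cutoff", {
  mito <- genome("m", rand_seq(20000, seed = 111))
  plast <- genome("p", rand_seq(15000, seed = 112))
  expect_identical(nrow(mipt_scan(mito, plast)$intervals), 0L)

  # planted plastome segments of 150, 500 and 2000 bp (plus an 80 bp one
  # that must be excluded by the >= 100 bp rule)
  s <- mito$sequence
  s <- insert_at(s, 2000, substr(plast$sequence, 1001, 1150))
  s <- insert_at(s, 8000, substr(plast$sequence, 5001, 5500))
  s <- insert_at(s, 14000, substr(plast$sequence, 9001, 11000))
  s <- insert_at(s, 18000, substr(plast$sequence, 13001, 13080))
  mr <- mipt_scan(genome("m2", s), plast)
  expect_identical(nrow(mr$intervals), 3L)
  expect_equal(mr$total_bp, 2650, tolerance = 40 / 2650)
  expect_true(all(mr$mipts$length >= 100))
})

test_that("decay_analysis: degenerate and monotone cases", {
  ids <- c("a", "b", "c", "d")
  mk <- function(bp) {
    m <- matrix(bp, 4, 4, byrow = TRUE, dimnames = list(ids, ids))
    diag(m) <- 100
    structure(list(genome_ids = ids, shared_bp = m * 1000,
                   shared_pct = m), class = "SharedDNAMatrix")
  }
  dist <- matrix(0, 4, 4, dimnames = list(ids, ids))
  dist[upper.tri(dist)] <- c(0.01, 0.02, 0.04, 0.03, 0.05, 0.06)
  dist <- dist + t(dist)

  # constant shared DNA: no variance, r reported as 0
  dc <- decay_analysis(mk(60), dist)
  expect_equal(dc$pearson_r, rep(0, 4))

  # strictly decreasing shared vs distance: Spearman -1 and an
  # interpolated half-life between the bracketing subjects
  m <- mk(60)
  m$shared_pct["a", c("b", "c", "d")] <- c(80, 60, 20)
  m$shared_bp["a", c("b", "c", "d")] <- c(80, 60, 20) * 1000
  dc2 <- decay_analysis(m, dist)
  expect_equal(dc2$spearman_rho[1], -1)
  # upper.tri fill gives a's subjects k2p 0.01/0.02/0.03 at 80/60/20%:
  # crossing 50% between 0.02 (60%) and 0.03 (20%) at 0.0225
  expect_equal(dc2$half_life_k2p[1], 0.0225, tolerance = 1e-9)
})

test_that("hgt_profile and profile_consistency behave as contracts state", {
  cfg <- simulation_config(seed = 121)
  sim <- evolve(cfg)
  subj <- sim$genomes

  # query identical to one subject: that subject's shared_bp = query length
  prof <- hgt_profile(sim$genomes$C, subj[setdiff(names(subj), "C")])
  self_prof <- hgt_profile(sim$genomes$C, subj)
  expect_identical(self_prof$putative_donor, "C")
  expect_equal(self_prof$shared_bp_by_subject[["C"]],
               sim$genomes$C$length_bp)

  expect_error(hgt_profile(sim$genomes$A, subj["B"]), ">= 2 subjects")

  # identical profiles -> 100%; elementwise halving -> 50%
  pc <- profile_consistency(prof, prof)
  expect_equal(pc$mean_consistency_pct, 100)
  half <- prof
  half$shared_bp_by_subject <- 0.5 * prof$shared_bp_by_subject
  expect_equal(profile_consistency(half, prof)$mean_consistency_pct, 50)
  # antisymmetry under swap
  ab <- profile_consistency(half, prof)$per_subject
  ba <- profile_consistency(prof, half)$per_subject
  expect_equal(ab * ba[names(ab)], rep(100^2, length(ab)),
               ignore_attr = TRUE)
})
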