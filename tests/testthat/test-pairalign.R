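test_that("Karlin-Altschul lambda: closed form, oracle, invalid regimes", {
  # +1/-1 uniform: 0.25 e^l + 0.75 e^-l = 1 solves exactly at e^l = 3
  ka <- solve_karlin_altschul(scoring_scheme(1, -1))
  expect_equal(ka$lam, log(3), tolerance = 1e-9)

  # +2/-3 uniform against an independent scalar-root oracle
  ka23 <- solve_karlin_altschul(scoring_scheme(2, -3))
  oracle <- stats::uniroot(function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1,
                           c(1e-9, 5), tol = 1e-12)$root
  expect_equal(ka23$lam, oracle, tolerance = 1e-6)

  # nonnegative expected score is not a valid Karlin-Altschul regime
  expect_error(scoring_scheme(1, 1), "invalid scoring scheme")
  expect_error(scoring_scheme(-1, -2), "invalid scoring scheme")

  # root actually solves the defining equation
  p <- 0.25
  expect_equal(p * exp(ka23$lam * 2) + (1 - p) * exp(ka23$lam * -3), 1,
               tolerance = 1e-9)
})

test_that("find_hsps: self-hit, planted copy, clean nulls", {
  g <- genome("g", rand_seq(5000, seed = 11))
  h <- find_hsps(g, g)
  full <- h[h$strand == "+" & h$qstart == 0 & h$qend == 5000, ]
  expect_identical(nrow(full), 1L)
  expect_equal(full$identity, 1)
  expect_identical(full$sstart, 0L)

  # exact 200 bp copy from position 100 planted at 700: one reciprocal
  # off-diagonal pair covering the planted copies
  base <- rand_seq(1000, seed = 12)
  s <- paste0(substr(base, 1, 700), substr(base, 101, 300),
              substr(base, 701, 1000))
  h2 <- find_hsps(genome("p", s), genome("p", s), self = TRUE)
  h2 <- h2[h2$strand == "+", ]
  expect_identical(nrow(h2), 2L)
  fwd <- h2[h2$qstart < h2$sstart, ]
  expect_lte(fwd$qstart, 100); expect_gte(fwd$qend, 300)
  expect_lte(fwd$sstart, 700); expect_gte(fwd$send, 900)
  expect_lte(fwd$length, 200 + 14) # at most word-scale boundary slack
  # reciprocal duplicate mirrors coordinates
  rev <- h2[h2$qstart > h2$sstart, ]
  expect_identical(rev$qstart, fwd$sstart)
  expect_identical(rev$send, fwd$qend)

  # two unrelated 1 kb sequences: nothing at 1e-6, and the SW oracle
  # confirms no local alignment reaches the score threshold
  a <- rand_seq(1000, seed = 13); b <- rand_seq(1000, seed = 14)
  h3 <- find_hsps(genome("a", a), genome("b", b))
  expect_identical(nrow(h3), 0L)
  ka <- solve_karlin_altschul(scoring_scheme())
  s_star <- evalue_score_threshold(1e-6, ka, 1000, 1000)
  expect_lt(local_align(a, b)$score, s_star)
})

test_that("strand symmetry: reverse-complementing the subject flips hits", {
  q <- rand_seq(800, seed = 21)
  seg <- substr(q, 201, 400)
  s <- insert_at(rand_seq(600, seed = 22), 300, reverse_complement(seg))
  h_fwd <- find_hsps(genome("q", q), genome("s", s))
  h_rc <- find_hsps(genome("q", q), genome("src", reverse_complement(s)))
  expect_identical(nrow(h_fwd), nrow(h_rc))
  expect_setequal(h_fwd$strand, "-")
  expect_setequal(h_rc$strand, "+")
  n <- nchar(s)
  expect_identical(sort(h_fwd$sstart), sort(n - h_rc$send))
  expect_identical(sort(h_fwd$send), sort(n - h_rc$sstart))
  expect_identical(sort(h_fwd$score), sort(h_rc$score))
})

test_that("stored E-values reproduce K*m*n*exp(-lambda*S) and cutoffs hold", {
  q <- genome("q", rand_seq(2000, seed = 31))
  s <- genome("s", insert_at(rand_seq(1500, seed = 32), 700,
                             substr(q$sequence, 501, 900)))
  h <- find_hsps(q, s)
  expect_gt(nrow(h), 0)
  ka <- attr(h, "ka")
  expect_equal(h$evalue,
               ka$K * 2000 * 1900 * exp(-ka$lam * h$score),
               tolerance = 1e-9)
  expect_true(all(h$evalue <= 1e-6))
  expect_true(all(h$length >= 30))
  # identity * length is an integer match count
  expect_equal(h$identity * h$length, round(h$identity * h$length))
})

test_that("global_align: identity, hand-filled DP case, empty sequence", {
  sc <- scoring_scheme(1, -1, 2, 1)
  r <- global_align("ACGTACGT", "ACGTACGT", sc)
  expect_identical(r$score, 8L)
  expect_equal(r$identity, 1)

  # hand-filled DP: ACGT vs ACT, best is AC-T: 3 matches - gap_open(2) = 1
  r2 <- global_align("ACGT", "ACT", sc)
  expect_identical(r2$score, 1L)
  expect_identical(nchar(r2$a), 4L)

  # all-gap alignment forced by the affine convention
  r3 <- global_align("ACGTA", "", sc)
  expect_identical(r3$score, -(2L + 4L * 1L))
  expect_identical(r3$b, "-----")
})

test_that("local_align oracle recovers planted exact segments", {
  bg1 <- rand_seq(900, seed = 41)
  bg2 <- rand_seq(900, seed = 42)
  seg <- rand_seq(150, seed = 43)
  a <- insert_at(bg1, 200, seg)
  b <- insert_at(bg2, 600, seg)
  al <- local_align(a, b)
  expect_gte(al$score, 150) # the planted run scores at least its length
  expect_gte(interval_overlap(al$qstart, al$qend, 200, 350), 150 * 0.95)
  expect_gte(interval_overlap(al$sstart, al$send, 600, 750), 150 * 0.95)
})

test_that("find_hsps is deterministic and sorted", {
  g <- genome("g", rand_seq(3000, seed = 51))
  s <- genome("s", insert_at(rand_seq(2500, seed = 52), 100,
                             substr(g$sequence, 1001, 1600)))
  h1 <- find_hsps(g, s); h2 <- find_hsps(g, s)
  expect_identical(h1, h2)
  expect_true(!is.unsorted(h1$qstart))
})
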