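make_cds <- function(ncod, seed) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, ncod - 2, replace = TRUE), "TAA"),
        collapse = "")
}

test_that("classify_gene: intact / pseudogene / fragment / absent", {
  ref <- make_cds(200, 131) # 600 bp CDS
  bg <- rand_seq(6000, seed = 132)

  expect_error(classify_gene(genome("g", bg), paste0(ref, "AC")),
               "divisible by 3")

  # verbatim insertion -> intact
  gi <- genome("gi", insert_at(bg, 2500, ref))
  expect_identical(classify_gene(gi, ref, "x")$status, "intact")

  # one internal base deleted -> frameshift -> pseudogene
  fs <- paste0(substr(ref, 1, 300), substr(ref, 302, nchar(ref)))
  gf <- genome("gf", insert_at(bg, 2500, fs))
  expect_identical(classify_gene(gf, ref, "x")$status, "pseudogene")

  # substitution creating an internal stop -> pseudogene
  stopped <- ref
  substr(stopped, 301, 303) <- "TAA"
  gs <- genome("gs", insert_at(bg, 2500, stopped))
  expect_identical(classify_gene(gs, ref, "x")$status, "pseudogene")

  # an 80 bp sub-segment only: suppressed, reported absent
  ga <- genome("ga", insert_at(bg, 2500, substr(ref, 201, 280)))
  expect_identical(classify_gene(ga, ref, "x")$status, "absent")

  # ~40% of the reference present, clean frame: truncated -> pseudogene
  gh <- genome("gh", insert_at(bg, 2500, substr(ref, 1, 240)))
  expect_identical(classify_gene(gh, ref, "x")$status, "pseudogene")

  # ~25% of the reference present -> fragment
  gq <- genome("gq", insert_at(bg, 2500, substr(ref, 1, 150)))
  expect_identical(classify_gene(gq, ref, "x")$status, "fragment")

  # no similarity at all -> absent
  expect_identical(classify_gene(genome("gn", bg), ref, "x")$status, "absent")

  # reverse-strand copy is found and intact
  gr <- genome("gr", insert_at(bg, 2500, reverse_complement(ref)))
  mr <- classify_gene(gr, ref, "x")
  expect_identical(mr$status, "intact")
  expect_identical(mr$strand, "-")
})

test_that("intron detection and intron_lengths", {
  # pure arithmetic on a hand-built model: exons [100,200) and [500,600)
  m <- structure(list(gene_name = "g", status = "intact", coverage = 1,
                      strand = "+",
                      exons = data.frame(start = c(100L, 500L),
                                         end = c(200L, 600L)),
                      introns = data.frame(start = 200L, end = 500L),
                      n_hits = 2L), class = "GeneModel")
  expect_identical(intron_lengths(m), 300L)

  # gene split by a planted intron: classified intact, intron recovered
  ref <- make_cds(300, 141) # 900 bp
  bg <- rand_seq(8000, seed = 142)
  intron <- rand_seq(700, seed = 143)
  gene_in_genome <- paste0(substr(ref, 1, 450), intron,
                           substr(ref, 451, 900))
  gg <- genome("gg", insert_at(bg, 3000, gene_in_genome))
  mg <- classify_gene(gg, ref, "g")
  expect_identical(mg$status, "intact")
  il <- intron_lengths(mg)
  expect_length(il, 1)
  expect_equal(il, 700, tolerance = 20 / 700)

  # planting 2900 bp more into the intron grows it by exactly that much
  intron2 <- paste0(substr(intron, 1, 350), rand_seq(2900, seed = 144),
                    substr(intron, 351, 700))
  gg2 <- genome("gg2", insert_at(bg, 3000, paste0(substr(ref, 1, 450),
                                                  intron2,
                                                  substr(ref, 451, 900))))
  il2 <- intron_lengths(classify_gene(gg2, ref, "g"))
  expect_equal(il2 - il, 2900, tolerance = 1e-6)

  # single-exon gene: no introns
  gi <- genome("gi", insert_at(bg, 3000, ref))
  expect_identical(intron_lengths(classify_gene(gi, ref, "g")), integer(0))
})

test_that("k2p: closed form, symmetry, pairwise deletion, saturation", {
  r0 <- k2p("ACGTACGT", "ACGTACGT")
  expect_equal(r0$d, 0)

  # P = 0.1, Q = 0.05 over 1000 sites: d = -ln(0.75)/2 - ln(0.9)/4
  a <- strrep("A", 1000)
  b <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", 850))
  rb <- k2p(a, b)
  expect_equal(rb$P, 0.1); expect_equal(rb$Q, 0.05)
  expect_equal(rb$d, 0.1701812, tolerance = 1e-6)
  expect_equal(rb$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)

  # symmetric, and correction inflates relative to raw mismatch fraction
  expect_identical(k2p(a, b)$d, k2p(b, a)$d)
  expect_gte(rb$d, 0.15)

  # gap and N columns are excluded
  rg <- k2p("AC-GTN", "ACCGTA")
  expect_identical(rg$sites_used, 4L)

  # saturation
  expect_error(k2p(strrep("A", 100), strrep("G", 100)),
               "saturated")
})

test_that("concatenate_genes: additivity, missing genes, degenerate input", {
  al <- list(g1 = list(a = rand_seq(300, 151), b = rand_seq(300, 152)),
             g2 = list(a = rand_seq(600, 153), b = rand_seq(600, 154)))
  cc <- concatenate_genes(al, c("g1", "g2"))
  expect_identical(nchar(cc$a), 900L)
  expect_identical(cc$boundaries$end, c(300L, 900L))
  expect_warning(concatenate_genes(al, c("g1", "g2", "g3")), "g3")
  expect_error(concatenate_genes(al, character(0)), "empty gene list")
})

test_that("K2P on concatenated simulated genes recovers the branch sum", {
  # two leaves at total path 0.05, no spacer turnover
  cfg <- simulation_config(tree = "(A:0.025,B:0.025);", igs_turnover = 0,
                           repeat_events = list(), mipt_events = list(),
                           seed = 161)
  sim <- evolve(cfg)
  gene_seqs <- lapply(sim$genomes, function(g) {
    out <- character(0)
    for (gn in names(sim$gene_refs)) {
      m <- classify_gene(g, sim$gene_refs[[gn]], gn)
      if (nrow(m$exons) == 1)
        out[gn] <- substr(g$sequence, m$exons$start[1] + 1, m$exons$end[1])
    }
    out
  })
  d <- k2p_matrix(gene_seqs)["A", "B"]
  # ~15 kb of coding sites: 3 binomial SEs around the true 0.05, plus the
  # small downward bias from stop-codon rejection in the simulator
  se <- sqrt(0.05 / 15000)
  expect_equal(d, 0.05, tolerance = (3 * se + 0.004) / 0.05)
})
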