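#' Simulation configuration for a mitogenome family
#'
#' The generator's stated world: a conserved genic core embedded in
#' fast-turnover intergenic spacers (IGS), evolved along a phylogeny whose
#' branch lengths are in expected substitutions per site. Point
#' substitutions follow the Kimura two-parameter process (transition /
#' transversion rate ratio `kappa`); IGS is additionally replaced wholesale
#' in segments (exponential lengths, mean `igs_segment_mean`) so that the
#' probability a spacer base survives a branch of length b is
#' `exp(-igs_turnover * b)`. Genes are never replaced and substitutions
#' that would create an internal stop codon (or destroy the start/stop)
#' are rejected, emulating purifying selection on the coding core.
#'
#' The desk-scale defaults (60 kb genome, 30 genes of 500 bp = 15 kb core)
#' keep the full pipeline running in seconds; `genome_len` can be raised to
#' paper scale (~400 kb). The default `igs_turnover` of 100 per unit branch
#' length makes spacers decay orders of magnitude faster than coding
#' sequence diverges, reproducing the short shared-DNA half-life seen in
#' real plant mitogenome comparisons.
#'
#' @param tree newick string (or `phylo`) with branch lengths in expected
#'   substitutions/site.
#' @param genome_len ancestor length, bp.
#' @param gene_set named integer vector of gene CDS lengths (multiples
#'   of 3).
#' @param kappa transition/transversion rate ratio.
#' @param igs_turnover IGS replacement intensity per unit branch length.
#' @param igs_segment_mean mean replaced-segment length, bp.
#' @param repeat_events list of repeat events, each
#'   `list(length=, copies=, type="dispersed"|"tandem", leaf=NULL)`;
#'   `leaf = NULL` applies the event independently in every leaf.
#' @param mipt_events list of `list(length=, leaf=NULL)` plastome-derived
#'   insertions (drawn from one synthetic plastome).
#' @param hgt_events list of `list(donor=, recipient=, tract_bp=)`.
#' @param plastome_len synthetic plastome length, bp.
#' @param seed integer master seed; all per-branch and per-event streams
#'   are derived from it by stable label hashing.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(
    tree = "(((((A:0.0010,B:0.0018):0.0011,C:0.0025):0.0013,D:0.0046):0.0017,E:0.0090):0.0023,F:0.0120);",
    genome_len = 60000L,
    gene_set = stats::setNames(rep(501L, 30L), sprintf("gene%02d", 1:30)),
    kappa = 2.0,
    igs_turnover = 100,
    igs_segment_mean = 2000,
    repeat_events = list(list(length = 2000L, copies = 3L, type = "dispersed"),
                         list(length = 51L, copies = 4L, type = "tandem")),
    mipt_events = list(list(length = 500L)),
    hgt_events = list(),
    plastome_len = 30000L,
    seed = 1L) {
  stopifnot(genome_len > sum(gene_set), all(gene_set %% 3 == 0),
            kappa > 0, igs_turnover >= 0, igs_segment_mean > 0)
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("malformed newick tree")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  structure(list(tree = phy, genome_len = as.integer(genome_len),
                 gene_set = gene_set, kappa = kappa,
                 igs_turnover = igs_turnover,
                 igs_segment_mean = igs_segment_mean,
                 repeat_events = repeat_events, mipt_events = mipt_events,
                 hgt_events = hgt_events,
                 plastome_len = as.integer(plastome_len),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

# stable 31-adic string hash for per-branch RNG substreams
label_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

substream_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + label_hash(label)) %% 2147483629)
}

mrca_of <- function(phy, i, j) ape::getMRCA(phy, c(i, j))

#' Mutate a sequence under the Kimura two-parameter process
#'
#' Applies the exact K2P transition probabilities for one branch of length
#' `t` expected substitutions/site with transition/transversion rate ratio
#' `kappa` (rates normalized so the total rate is 1).
#'
#' @param x sequence string or character vector of bases.
#' @param t branch length, expected substitutions per site.
#' @param kappa transition/transversion rate ratio.
#' @return mutated sequence in the same representation as the input.
#' @export
mutate_k2p <- function(x, t, kappa = 2.0) {
  was_string <- is.character(x) && length(x) == 1L && nchar(x[1]) > 1L
  v <- if (was_string) strsplit(x, "")[[1]] else x
  alpha <- kappa / (kappa + 2); beta <- 1 / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * t)
  r <- stats::runif(length(v))
  is_base <- v %in% BASES
  ts <- is_base & r < p_ts
  tv <- is_base & r >= p_ts & r < p_ts + p_tv
  if (any(ts)) v[ts] <- TS_PARTNER[v[ts]]
  if (any(tv)) {
    pick <- stats::runif(sum(tv)) < 0.5
    v[tv] <- mapply(function(b, first) TV_PARTNERS[[b]][if (first) 1 else 2],
                    v[tv], pick, USE.NAMES = FALSE)
  }
  if (was_string) paste(v, collapse = "") else v
}

# random CDS: ATG + non-stop codons + stop
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len / 3
  sense <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
                   STOP_CODONS)
  mid <- sample(sense, ncod - 2L, replace = TRUE)
  paste(c("ATG", mid, sample(STOP_CODONS, 1L)), collapse = "")
}

# revert codons whose evolution created internal stops / broke start or stop
repair_gene <- function(child, parent, start, end) {
  idx <- seq.int(start + 1L, end)
  g <- child[idx]; gp <- parent[idx]
  ncod <- length(g) / 3
  cod <- matrix(g, nrow = 3)
  codstr <- apply(cod, 2, paste, collapse = "")
  bad <- which(codstr %in% STOP_CODONS)
  bad <- bad[bad < ncod] # terminal stop is fine
  if (codstr[1] != "ATG") bad <- c(bad, 1L)
  if (!(codstr[ncod] %in% STOP_CODONS)) bad <- c(bad, ncod)
  for (k in unique(bad)) {
    pos <- (k - 1L) * 3L + 1:3
    g[pos] <- gp[pos]
  }
  child[idx] <- g
  child
}

# state for one node: seq (char vector), surv (logical over ancestral coords)
# genes: data.frame(gene,start,end) 0-based half-open, valid pre-events.

#' Evolve a synthetic mitogenome family with ground truth
#'
#' Draws a uniform-random ancestor with the configured gene core, evolves
#' it along the tree (K2P substitutions plus segmental IGS replacement),
#' then applies repeat / plastome-insertion (MIPT) / horizontal-transfer
#' events at the leaves. Every downstream measurement has a matching truth
#' record.
#'
#' @param config a [simulation_config()].
#' @return list with
#'   `genomes` (named list of `Genome`),
#'   `plastome` (synthetic plastome `Genome`),
#'   `gene_refs` (named vector: ancestral CDS per gene),
#'   `genes` (per leaf: gene coordinate data.frame),
#'   `truth`: list with `distance` (true pairwise tree distance),
#'     `shared_bp` / `shared_frac` (ancestral bases surviving on both
#'     lineages; fraction is of the query genome length), `surv` (per-leaf
#'     survival masks over ancestral coordinates), and per-leaf `repeats`,
#'     `tandems`, `mipts`, `hgt` interval tables.
#' @export
evolve <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  phy <- config$tree
  nleaf <- length(phy$tip.label)
  set.seed(substream_seed(config$seed, "ancestor"))

  # ancestor layout: igs gene igs gene ... igs
  glens <- config$gene_set
  igs_total <- config$genome_len - sum(glens)
  ngap <- length(glens) + 1L
  gap <- rep(igs_total %/% ngap, ngap)
  gap[ngap] <- gap[ngap] + igs_total - sum(gap)
  gene_refs <- vapply(glens, random_cds, character(1))
  pieces <- character(0); genes <- data.frame()
  pos <- 0L
  anc <- character(0)
  for (i in seq_along(glens)) {
    igs <- sample(BASES, gap[i], replace = TRUE)
    anc <- c(anc, igs)
    gs <- length(anc)
    anc <- c(anc, strsplit(gene_refs[i], "")[[1]])
    genes <- rbind(genes, data.frame(gene = names(glens)[i], start = gs,
                                     end = length(anc),
                                     stringsAsFactors = FALSE))
  }
  anc <- c(anc, sample(BASES, gap[ngap], replace = TRUE))
  L0 <- length(anc)
  gene_mask <- rep(FALSE, L0)
  for (i in seq_len(nrow(genes)))
    gene_mask[seq.int(genes$start[i] + 1L, genes$end[i])] <- TRUE
  igs_idx <- which(!gene_mask)
  # IGS block id per position, for clipping replacement segments
  blk <- cumsum(c(TRUE, diff(igs_idx) > 1L))

  set.seed(substream_seed(config$seed, "plastome"))
  plastome <- genome("plastome",
                     paste(sample(BASES, config$plastome_len, replace = TRUE),
                           collapse = ""), circular = TRUE)

  # tree traversal
  lab <- c(phy$tip.label, paste0("node", seq_len(phy$Nnode)))
  root <- nleaf + 1L
  states <- vector("list", nleaf + phy$Nnode)
  states[[root]] <- list(seq = anc, surv = rep(TRUE, L0))
  ord <- phy$edge[order(phy$edge[, 1]), , drop = FALSE] # parent-major order
  # preorder: process edges so parent state exists (ape edge rows are fine
  # when traversed from the root; use reorder for safety)
  edges <- ape::reorder.phylo(phy, "cladewise")$edge
  elens <- ape::reorder.phylo(phy, "cladewise")$edge.length
  branch_replaced <- vector("list", nleaf + phy$Nnode) # keyed by child node
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; chd <- edges[k, 2]; bl <- elens[k]
    st <- states[[par]]
    set.seed(substream_seed(config$seed, paste0("branch:", lab[chd])))
    child <- mutate_k2p(st$seq, bl, config$kappa)
    for (i in seq_len(nrow(genes)))
      child <- repair_gene(child, st$seq, genes$start[i], genes$end[i])
    surv <- st$surv
    replaced <- rep(FALSE, length(igs_idx))
    if (config$igs_turnover > 0 && bl > 0) {
      p_rep <- 1 - exp(-config$igs_turnover * bl)
      target <- round(p_rep * length(igs_idx))
      guard <- 0L
      while (sum(replaced) < target && guard < 10000L) {
        guard <- guard + 1L
        a <- sample.int(length(igs_idx), 1L)
        len <- max(1L, round(stats::rexp(1L, 1 / config$igs_segment_mean)))
        b <- min(length(igs_idx), a + len - 1L)
        sel <- a:b
        sel <- sel[blk[sel] == blk[a]] # stay within one IGS block
        replaced[sel] <- TRUE
      }
      ridx <- igs_idx[replaced]
      if (length(ridx)) {
        child[ridx] <- sample(BASES, length(ridx), replace = TRUE)
        surv[ridx] <- FALSE
      }
    }
    branch_replaced[[chd]] <- replaced
    states[[chd]] <- list(seq = child, surv = surv)
  }

  # leaf states + events
  leaves <- phy$tip.label
  out <- list()
  for (li in seq_along(leaves)) {
    nm <- leaves[li]
    st <- states[[li]]
    out[[nm]] <- list(seq = st$seq, surv = st$surv,
                      anc_id = ifelse(st$surv | gene_mask, seq_len(L0), 0L),
                      genes = genes,
                      repeats = data.frame(start = integer(0), end = integer(0),
                                           role = character(0)),
                      tandems = data.frame(start = integer(0), end = integer(0),
                                           period = integer(0)),
                      mipts = data.frame(start = integer(0), end = integer(0),
                                         p_start = integer(0), p_end = integer(0)),
                      hgt = data.frame(start = integer(0), end = integer(0),
                                       donor = character(0)))
  }

  shift_df <- function(df, at, by) {
    if (nrow(df) == 0L) return(df)
    df$start <- ifelse(df$start >= at, df$start + by, df$start)
    df$end <- ifelse(df$end > at, df$end + by, df$end)
    df
  }
  insert_seg <- function(ls, at, seg) {
    n <- length(seg)
    ls$seq <- append(ls$seq, seg, after = at)
    ls$anc_id <- append(ls$anc_id, rep(0L, n), after = at)
    ls$genes <- shift_df(ls$genes, at, n)
    ls$repeats <- shift_df(ls$repeats, at, n)
    ls$tandems <- shift_df(ls$tandems, at, n)
    ls$mipts <- shift_df(ls$mipts, at, n)
    ls$hgt <- shift_df(ls$hgt, at, n)
    ls
  }
  igs_positions <- function(ls) {
    # insertion points outside genes
    mask <- rep(TRUE, length(ls$seq) + 1L)
    for (i in seq_len(nrow(ls$genes)))
      mask[seq.int(ls$genes$start[i] + 1L, ls$genes$end[i]) + 1L] <- FALSE
    which(mask) - 1L
  }

  ev_leaves <- function(ev) if (is.null(ev$leaf)) leaves else ev$leaf
  for (ei in seq_along(config$repeat_events)) {
    ev <- config$repeat_events[[ei]]
    for (nm in ev_leaves(ev)) {
      set.seed(substream_seed(config$seed, paste0("rep", ei, ":", nm)))
      ls <- out[[nm]]
      if (identical(ev$type, "tandem")) {
        motif <- sample(BASES, ev$length, replace = TRUE)
        arr <- rep(motif, ev$copies)
        at <- sample(igs_positions(ls), 1L)
        ls <- insert_seg(ls, at, arr)
        ls$tandems <- rbind(ls$tandems,
                            data.frame(start = at, end = at + length(arr),
                                       period = as.integer(ev$length)))
      } else {
        src <- sample.int(length(ls$seq) - ev$length, 1L)
        seg <- ls$seq[seq.int(src + 1L, src + ev$length)]
        ls$repeats <- rbind(ls$repeats,
                            data.frame(start = src, end = src + ev$length,
                                       role = "source"))
        for (cp in seq_len(ev$copies - 1L)) {
          at <- sample(igs_positions(ls), 1L)
          ls <- insert_seg(ls, at, seg)
          ls$repeats <- rbind(ls$repeats,
                              data.frame(start = at, end = at + ev$length,
                                         role = "copy"))
        }
      }
      out[[nm]] <- ls
    }
  }
  for (ei in seq_along(config$mipt_events)) {
    ev <- config$mipt_events[[ei]]
    for (nm in ev_leaves(ev)) {
      set.seed(substream_seed(config$seed, paste0("mipt", ei, ":", nm)))
      ls <- out[[nm]]
      ps <- sample.int(config$plastome_len - ev$length, 1L)
      seg <- strsplit(substr(plastome$sequence, ps + 1L, ps + ev$length), "")[[1]]
      at <- sample(igs_positions(ls), 1L)
      ls <- insert_seg(ls, at, seg)
      ls$mipts <- rbind(ls$mipts,
                        data.frame(start = at, end = at + ev$length,
                                   p_start = ps, p_end = ps + ev$length))
      out[[nm]] <- ls
    }
  }
  for (ei in seq_along(config$hgt_events)) {
    ev <- config$hgt_events[[ei]]
    set.seed(substream_seed(config$seed, paste0("hgt", ei)))
    don <- out[[ev$donor]]; rec <- out[[ev$recipient]]
    src <- sample.int(length(don$seq) - ev$tract_bp, 1L)
    seg <- don$seq[seq.int(src + 1L, src + ev$tract_bp)]
    at <- sample(igs_positions(rec), 1L)
    rec <- insert_seg(rec, at, seg)
    rec$hgt <- rbind(rec$hgt, data.frame(start = at, end = at + ev$tract_bp,
                                         donor = ev$donor))
    out[[ev$recipient]] <- rec
  }

  genomes <- lapply(leaves, function(nm)
    genome(nm, paste(out[[nm]]$seq, collapse = ""), circular = TRUE))
  names(genomes) <- leaves

  dmat <- as.matrix(stats::cophenetic(phy))[leaves, leaves]
  surv_mat <- vapply(leaves, function(nm) out[[nm]]$surv | gene_mask,
                     logical(L0))
  # shared truth for a pair: ancestral bases not replaced on any branch of
  # the path between the two leaves (replacements before the MRCA leave
  # identical copies in both and therefore still count as shared)
  lens <- vapply(genomes, `[[`, numeric(1), "length_bp")
  shared_bp <- matrix(0, nleaf, nleaf, dimnames = list(leaves, leaves))
  diag(shared_bp) <- lens
  n_igs <- length(igs_idx)
  for (i in seq_len(nleaf - 1L)) {
    for (j in seq(i + 1L, nleaf)) {
      path <- ape::nodepath(phy, i, j)
      repl <- rep(FALSE, n_igs)
      for (nd in path) {
        # every node on the path except the MRCA is the child end of a
        # path edge; the MRCA is the unique path node that is an ancestor
        # of both tips, i.e. the one with the smallest depth
        if (!is.null(branch_replaced[[nd]]) && nd != mrca_of(phy, i, j))
          repl <- repl | branch_replaced[[nd]]
      }
      shared_bp[i, j] <- shared_bp[j, i] <- (L0 - n_igs) + sum(!repl)
    }
  }
  shared_frac <- shared_bp / lens
  diag(shared_frac) <- 1

  list(genomes = genomes, plastome = plastome, gene_refs = gene_refs,
       genes = lapply(out, `[[`, "genes"),
       truth = list(distance = dmat, shared_bp = shared_bp,
                    shared_frac = shared_frac, surv = surv_mat,
                    ancestor_len = L0,
                    repeats = lapply(out, `[[`, "repeats"),
                    tandems = lapply(out, `[[`, "tandems"),
                    mipts = lapply(out, `[[`, "mipts"),
                    hgt = lapply(out, `[[`, "hgt")),
       config = config)
}

#' Build a synthetic parasite genome from a donor leaf
#'
#' The parasite is a mosaic of tracts sampled from the donor genome plus
#' unrelated random background, emulating massive mitochondrion-to-
#' mitochondrion horizontal transfer into a holoparasite. Truth records the
#' donor identity and tract intervals on both sides.
#'
#' @param sim result of [evolve()].
#' @param donor donor leaf label.
#' @param tract_bp total donor-derived bp (0 allowed: pure background).
#' @param background_bp total unrelated random bp.
#' @param chunk_bp approximate tract chunk size.
#' @param id parasite genome id.
#' @param seed integer seed.
#' @return list with `genome` (the parasite `Genome`), `donor`, and
#'   `tracts` (data.frame of parasite-side and donor-side intervals).
#' @export
make_parasite <- function(sim, donor, tract_bp, background_bp = 20000L,
                          chunk_bp = 10000L, id = "parasite", seed = 1L) {
  if (!donor %in% names(sim$genomes)) stop("unknown donor leaf: ", donor)
  dseq <- sim$genomes[[donor]]$sequence
  dlen <- nchar(dseq)
  if (tract_bp > dlen) stop("tract_bp exceeds donor length")
  set.seed(substream_seed(seed, paste0("parasite:", donor)))
  nchunk <- if (tract_bp == 0) 0L else max(1L, round(tract_bp / chunk_bp))
  sizes <- if (nchunk > 0) {
    s <- rep(tract_bp %/% nchunk, nchunk)
    s[1] <- s[1] + tract_bp - sum(s)
    s
  } else integer(0)
  # non-overlapping donor starts
  starts <- integer(0)
  for (sz in sizes) {
    ok <- FALSE; guard <- 0L
    while (!ok && guard < 1000L) {
      guard <- guard + 1L
      a <- sample.int(dlen - sz, 1L)
      ok <- !any(a < starts + sizes[seq_along(starts)] & a + sz > starts)
    }
    starts <- c(starts, a)
  }
  nbg <- nchunk + 1L
  bg_sizes <- rep(background_bp %/% nbg, nbg)
  bg_sizes[1] <- bg_sizes[1] + background_bp - sum(bg_sizes)
  pieces <- character(0); tracts <- data.frame(); pos <- 0L
  for (k in seq_len(nbg)) {
    if (bg_sizes[k] > 0) {
      pieces <- c(pieces, paste(sample(BASES, bg_sizes[k], replace = TRUE),
                                collapse = ""))
      pos <- pos + bg_sizes[k]
    }
    if (k <= nchunk) {
      seg <- substr(dseq, starts[k] + 1L, starts[k] + sizes[k])
      pieces <- c(pieces, seg)
      tracts <- rbind(tracts,
                      data.frame(start = pos, end = pos + sizes[k],
                                 donor_start = starts[k],
                                 donor_end = starts[k] + sizes[k]))
      pos <- pos + sizes[k]
    }
  }
  list(genome = genome(id, paste(pieces, collapse = ""), circular = FALSE),
       donor = donor, tracts = tracts)
}
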