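#' Classify one ancestral mitochondrial protein-coding gene in a genome
#'
#' The reference CDS is searched against the genome on both strands with
#' the seed-and-extend aligner; hits shorter than `min_fragment` bp are
#' suppressed. The surviving hits on the best strand are chained
#' co-linearly into a putative exon structure, and the gene is classified:
#'
#' * `intact`: chained hits cover >= `intact_cov` of the reference, the
#'   reconstructed coding sequence begins with `ATG`, is frame-preserving
#'   (every non-intron indel a multiple of 3) and has no internal stop;
#' * `pseudogene`: coverage >= `pseudo_cov` but a frame-disrupting indel or
#'   internal stop codon (or a missing start);
#' * `fragment`: retained hits but coverage below `pseudo_cov`;
#' * `absent`: no retained hit (sub-`min_fragment` fragments are
#'   suppressed, matching the convention that such fragments are not
#'   presented).
#'
#' Subject-side gaps of at least `min_intron` bp with a query-side gap of
#' at most 10 bp are treated as introns (spliced out, no frame penalty).
#'
#' @param g a `Genome`.
#' @param reference_cds reference coding sequence (length divisible by 3).
#' @param gene_name gene symbol for the report.
#' @param params [repeat_params()] controlling the search.
#' @param min_fragment hits shorter than this are suppressed (bp).
#' @param intact_cov,pseudo_cov reference-coverage thresholds.
#' @param min_intron minimal subject-side gap treated as an intron (bp).
#' @return object of class `GeneModel`: list with `gene_name`, `status`,
#'   `coverage`, `strand`, `exons` (genome intervals, 0-based half-open),
#'   `introns`, `n_hits`.
#' @export
classify_gene <- function(g, reference_cds, gene_name = "gene",
                          params = repeat_params(), min_fragment = 100L,
                          intact_cov = 0.9, pseudo_cov = 0.3,
                          min_intron = 50L) {
  g <- as_genome(g, "genome")
  ref <- normalize_sequence(reference_cds)
  if (nchar(ref) %% 3 != 0)
    stop("reference CDS length not divisible by 3 for gene ", gene_name)
  ref_len <- nchar(ref)
  model <- function(status, coverage = 0, strand = NA_character_,
                    exons = data.frame(start = integer(0), end = integer(0)),
                    n_hits = 0L) {
    introns <- if (nrow(exons) >= 2) {
      data.frame(start = exons$end[-nrow(exons)], end = exons$start[-1L])
    } else data.frame(start = integer(0), end = integer(0))
    structure(list(gene_name = gene_name, status = status,
                   coverage = coverage, strand = strand, exons = exons,
                   introns = introns, n_hits = n_hits),
              class = "GeneModel")
  }
  hits <- find_hsps(genome(gene_name, ref, circular = FALSE), g,
                    word_size = params$word_size,
                    evalue_max = params$evalue_max, scheme = params$scheme,
                    min_len = params$min_repeat_len)
  hits <- hits[hits$length >= min_fragment, , drop = FALSE]
  if (nrow(hits) == 0L) return(model("absent"))
  # pick the strand with the larger reference coverage
  cov_by_strand <- vapply(c("+", "-"), function(st) {
    h <- hits[hits$strand == st, , drop = FALSE]
    interval_union_length(data.frame(start = h$qstart, end = h$qend)) / ref_len
  }, numeric(1))
  st <- names(which.max(cov_by_strand))
  h <- hits[hits$strand == st, , drop = FALSE]
  # greedy co-linear chain by query position, best score first
  h <- h[order(-h$score), , drop = FALSE]
  chain <- h[1, , drop = FALSE]
  for (i in seq_len(nrow(h))[-1]) {
    cand <- h[i, ]
    ok <- all(apply(chain, 1, function(r) {
      qs <- as.integer(r[["qstart"]]); qe <- as.integer(r[["qend"]])
      ss <- as.integer(r[["sstart"]]); se <- as.integer(r[["send"]])
      qdisj <- cand$qend <= qs + 10L || cand$qstart >= qe - 10L
      colinear <- if (st == "+") {
        (cand$qstart >= qe - 10L) == (cand$sstart >= se - 10L)
      } else {
        (cand$qstart >= qe - 10L) == (cand$send <= ss + 10L)
      }
      qdisj && colinear
    }))
    if (ok) chain <- rbind(chain, cand)
  }
  chain <- chain[order(chain$qstart), , drop = FALSE]
  cov <- interval_union_length(
    data.frame(start = chain$qstart, end = chain$qend)) / ref_len
  exons <- data.frame(start = chain$sstart, end = chain$send)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (cov < pseudo_cov)
    return(model("fragment", cov, st, exons, nrow(chain)))

  # frame assessment on the reconstructed coding sequence
  disrupted <- FALSE
  if (nrow(chain) >= 2) {
    for (i in seq_len(nrow(chain) - 1L)) {
      qgap <- chain$qstart[i + 1L] - chain$qend[i]
      sgap <- if (st == "+") chain$sstart[i + 1L] - chain$send[i]
              else chain$sstart[i] - chain$send[i + 1L]
      is_intron <- sgap >= min_intron && abs(qgap) <= 10L
      if (!is_intron && (sgap - qgap) %% 3L != 0L) disrupted <- TRUE
    }
  }
  # splice matched genome sequence into the reference frame
  est <- ref
  for (i in seq_len(nrow(chain))) {
    seg <- substr(g$sequence, chain$sstart[i] + 1L, chain$send[i])
    if (st == "-") seg <- reverse_complement(seg)
    if (nchar(seg) == chain$qend[i] - chain$qstart[i])
      substr(est, chain$qstart[i] + 1L, chain$qend[i]) <- seg
  }
  aa <- translate_dna(est)
  internal_stop <- grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
  has_start <- substr(est, 1, 3) == "ATG"
  status <- if (cov >= intact_cov && !disrupted && !internal_stop && has_start)
    "intact" else "pseudogene"
  model(status, cov, st, exons, nrow(chain))
}

# minimal standard-code translation; codons with N translate to X
translate_dna <- function(x) {
  n <- nchar(x) %/% 3
  codons <- substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(vapply(codons, function(cd) {
    if (grepl("[^ACGT]", cd)) return("X")
    GENETIC_CODE_MIN[[cd]]
  }, character(1)), collapse = "")
}

GENETIC_CODE_MIN <- as.list(Biostrings::GENETIC_CODE)

#' Intron lengths of a classified gene model
#'
#' Gap lengths between consecutive exons on the genome; a single-exon gene
#' has no introns.
#'
#' @param model a `GeneModel` from [classify_gene()].
#' @return integer vector of intron lengths (bp), possibly empty.
#' @export
intron_lengths <- function(model) {
  stopifnot(inherits(model, "GeneModel"))
  if (nrow(model$introns) == 0L) return(integer(0))
  as.integer(model$introns$end - model$introns$start)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing a gap or an ambiguous base in either sequence are
#' excluded (pairwise deletion). With transition proportion P and
#' transversion proportion Q over the retained sites,
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' An error is raised when a logarithm argument is nonpositive
#' (saturation).
#'
#' @param aligned_a,aligned_b equal-length aligned sequence strings.
#' @return object of class `K2PResult`: list with `P`, `Q`, `d`,
#'   `sites_used`.
#' @export
k2p <- function(aligned_a, aligned_b) {
  a <- strsplit(normalize_sequence(aligned_a), "")[[1]]
  b <- strsplit(normalize_sequence(aligned_b), "")[[1]]
  if (length(a) != length(b)) stop("k2p: sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("k2p: no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("distance undefined: saturated")
  d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  structure(list(P = P, Q = Q, d = d, sites_used = n), class = "K2PResult")
}

#' Concatenate per-gene pairwise alignments
#'
#' Alignments are joined in the order of `gene_list`; genes missing from
#' the alignment set are skipped with a warning. Per-gene boundaries are
#' recorded for downstream partitioned analyses.
#'
#' @param alignments named list of pairwise alignments (each a list with
#'   aligned strings `a` and `b`, as returned by [global_align()]).
#' @param gene_list character vector fixing the gene order.
#' @return list with concatenated `a`, `b` and data.frame `boundaries`
#'   (`gene`, 0-based half-open `start`, `end` in alignment columns).
#' @export
concatenate_genes <- function(alignments, gene_list) {
  if (length(gene_list) == 0L) stop("concatenate_genes: empty gene list")
  present <- gene_list[gene_list %in% names(alignments)]
  missing <- setdiff(gene_list, present)
  if (length(missing))
    warning("genes missing from alignment set, skipped: ",
            paste(missing, collapse = ", "))
  if (length(present) == 0L) stop("concatenate_genes: no genes to concatenate")
  a <- character(0); b <- character(0); lens <- integer(0)
  for (gn in present) {
    al <- alignments[[gn]]
    stopifnot(nchar(al$a) == nchar(al$b))
    a <- c(a, al$a); b <- c(b, al$b); lens <- c(lens, nchar(al$a))
  }
  ends <- cumsum(lens)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       boundaries = data.frame(gene = present,
                               start = c(0L, ends[-length(ends)]),
                               end = ends, stringsAsFactors = FALSE))
}

#' Pairwise K2P distance matrix from per-genome gene sequences
#'
#' For each genome pair, the shared genes of `gene_list` are globally
#' aligned gene by gene, concatenated in fixed order and summarized with
#' [k2p()].
#'
#' @param gene_seqs named list (one element per genome) of named character
#'   vectors of gene coding sequences.
#' @param gene_list genes to use, in order (default: genes present in all
#'   genomes).
#' @param scheme [scoring_scheme()] for the per-gene global alignments.
#' @return symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(gene_seqs, gene_list = NULL,
                       scheme = scoring_scheme()) {
  ids <- names(gene_seqs)
  if (is.null(gene_list))
    gene_list <- Reduce(intersect, lapply(gene_seqs, names))
  if (length(gene_list) == 0L) stop("k2p_matrix: no shared genes")
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- gene_list[gene_list %in% names(gene_seqs[[i]]) &
                            gene_list %in% names(gene_seqs[[j]])]
      aln <- lapply(shared, function(gn)
        global_align(gene_seqs[[i]][[gn]], gene_seqs[[j]][[gn]], scheme))
      names(aln) <- shared
      cc <- concatenate_genes(aln, shared)
      d[i, j] <- d[j, i] <- k2p(cc$a, cc$b)$d
    }
  }
  d
}
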