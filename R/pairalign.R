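#' Nucleotide scoring scheme
#'
#' Match/mismatch rewards with affine gap costs and background base
#' frequencies. The defaults (+1/-2, gap open 5, extend 2, uniform
#' frequencies) stand in for unstated BLASTN defaults and are echoed into
#' every report header so results are reproducible. Karlin-Altschul theory
#' requires a negative expected per-position score and at least one positive
#' score; both are checked here.
#'
#' @param match positive integer match reward.
#' @param mismatch negative integer mismatch penalty.
#' @param gap_open nonnegative cost of a length-1 gap.
#' @param gap_extend positive cost per additional gap position.
#' @param base_freqs four probabilities (A,C,G,T) summing to 1.
#' @return an object of class `ScoringScheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                           gap_extend = 2L, base_freqs = rep(0.25, 4)) {
  stopifnot(length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-9,
            all(base_freqs > 0), gap_open >= 0, gap_extend > 0)
  if (match <= 0) stop("invalid scoring scheme: match reward must be positive")
  p_match <- sum(base_freqs^2)
  expected <- p_match * match + (1 - p_match) * mismatch
  if (expected >= 0)
    stop("invalid scoring scheme: expected per-position score must be negative")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 base_freqs = base_freqs),
            class = "ScoringScheme")
}

#' Solve Karlin-Altschul parameters for a scoring scheme
#'
#' lambda is the unique positive root of
#' \deqn{f(\lambda) = \sum_{i,j} p_i p_j e^{\lambda s_{ij}} - 1 = 0,}
#' found by bisection to absolute tolerance 1e-12. K is either fixed at 0.3
#' (default; it shifts E-values by a constant factor and the e-value cutoff
#' is configurable anyway) or approximated by the geometric-like series for
#' ungapped scoring, with the method recorded.
#'
#' @param scheme a [scoring_scheme()].
#' @param k_method `"fixed"` (K = 0.3) or `"series"`.
#' @return object of class `KarlinAltschulParams` with `lam`, `K`,
#'   `k_method`.
#' @export
solve_karlin_altschul <- function(scheme, k_method = c("fixed", "series")) {
  stopifnot(inherits(scheme, "ScoringScheme"))
  k_method <- match.arg(k_method)
  p <- scheme$base_freqs
  p_match <- sum(p^2)
  f <- function(lam) {
    p_match * exp(lam * scheme$match) +
      (1 - p_match) * exp(lam * scheme$mismatch) - 1
  }
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  lam <- (lo + hi) / 2
  K <- if (k_method == "fixed") 0.3 else {
    # crude high-score series approximation for ungapped integer scoring:
    # K ~ (expected e^{lam s} weighted decay); adequate because E-values are
    # only thresholded, never reported as exact NCBI values.
    q <- p_match * exp(lam * scheme$match)
    max(0.01, min(1, (1 - q)^2 / (lam * scheme$match)))
  }
  structure(list(lam = lam, K = K, k_method = k_method, scheme = scheme),
            class = "KarlinAltschulParams")
}

#' E-value of a score, and the score needed for an E-value cutoff
#'
#' `E = K * m * n * exp(-lambda * S)` over search space `m * n`
#' (no finite-size edge correction).
#'
#' @param score integer alignment score(s).
#' @param ka [solve_karlin_altschul()] result.
#' @param m,n query and subject lengths.
#' @return `hsp_evalue`: numeric E-value(s). `evalue_score_threshold`: the
#'   minimal integer score with E-value at or below `evalue_max`.
#' @export
hsp_evalue <- function(score, ka, m, n) {
  ka$K * as.numeric(m) * as.numeric(n) * exp(-ka$lam * score)
}

#' @rdname hsp_evalue
#' @param evalue_max E-value cutoff.
#' @export
evalue_score_threshold <- function(evalue_max, ka, m, n) {
  as.integer(ceiling(log(ka$K * as.numeric(m) * as.numeric(n) / evalue_max) /
                       ka$lam))
}

#' Reverse complement of a nucleotide string
#' @param x nucleotide string.
#' @return reverse-complemented string (N maps to N).
#' @export
reverse_complement <- function(x) cpp_revcomp(normalize_sequence(x))

#' Find high-scoring segment pairs (HSPs) between two genomes
#'
#' Exact-word seeding on both strands followed by ungapped X-drop extension,
#' the same seed-and-extend strategy as BLASTN. Seeds falling inside an
#' extension already emitted on the same diagonal are skipped (containment
#' dedup). HSPs are kept when their Karlin-Altschul E-value is at most
#' `evalue_max` and their aligned length is at least `min_len`, and returned
#' sorted by query start, then score descending.
#'
#' @param query,subject `Genome` objects (or plain sequence strings).
#' @param word_size exact seed length (>= 4); the repeat/shared-DNA analyses
#'   use 7, which with `evalue_max = 1e-6` detects repeats down to ~30 bp.
#' @param evalue_max E-value cutoff.
#' @param scheme a [scoring_scheme()].
#' @param min_len minimal aligned length retained.
#' @param xdrop ungapped X-drop termination parameter, in score units.
#' @param self logical; when `TRUE` (genome-vs-itself repeat scan) the
#'   trivial full-length main-diagonal self-hit is suppressed.
#' @return data.frame of class `hsp_table` with 0-based half-open `qstart`,
#'   `qend`, `sstart`, `send`, plus `strand`, `score`, `matches`, `length`,
#'   `identity`, `evalue`, and `qid`/`sid`.
#' @export
find_hsps <- function(query, subject, word_size = 7L, evalue_max = 1e-6,
                      scheme = scoring_scheme(), min_len = 30L, xdrop = 20L,
                      self = FALSE) {
  q <- as_genome(query, "query")
  s <- as_genome(subject, "subject")
  if (word_size < 4L) stop("word_size must be >= 4")
  if (q$length_bp == 0L || s$length_bp == 0L) stop("empty genome")
  empty <- data.frame(qid = character(0), sid = character(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), score = integer(0),
                      matches = integer(0), length = integer(0),
                      identity = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("hsp_table", "data.frame")
  if (word_size > min(q$length_bp, s$length_bp)) {
    warning("word_size exceeds a genome length; no seeds possible")
    return(empty)
  }
  ka <- solve_karlin_altschul(scheme)
  min_score <- evalue_score_threshold(evalue_max, ka, q$length_bp, s$length_bp)
  h <- cpp_find_hsps(q$sequence, s$sequence, as.integer(word_size),
                     scheme$match, scheme$mismatch, as.integer(xdrop),
                     min_score, as.integer(min_len), isTRUE(self), TRUE)
  if (nrow(h) == 0L) return(empty)
  h <- unique(h)
  h$length <- h$qend - h$qstart
  h$identity <- h$matches / h$length
  h$evalue <- hsp_evalue(h$score, ka, q$length_bp, s$length_bp)
  h <- h[h$evalue <= evalue_max, , drop = FALSE]
  h <- h[order(h$qstart, -h$score), , drop = FALSE]
  out <- cbind(data.frame(qid = q$id, sid = s$id, stringsAsFactors = FALSE), h)
  rownames(out) <- NULL
  class(out) <- c("hsp_table", "data.frame")
  attr(out, "ka") <- ka
  attr(out, "params") <- list(word_size = word_size, evalue_max = evalue_max,
                              min_len = min_len, xdrop = xdrop,
                              scheme = scheme)
  out
}

as_genome <- function(x, what) {
  if (inherits(x, "Genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome(what, x))
  stop(what, " must be a Genome or a single sequence string")
}

#' Optimal global alignment (Needleman-Wunsch / Gotoh)
#'
#' Affine gap cost open + (k-1)*extend; deterministic traceback with tie
#' order diagonal > up > left. Used for gene-by-gene comparisons feeding K2P
#' distances.
#'
#' @param a,b nonempty sequence strings.
#' @param scheme a [scoring_scheme()].
#' @return list with aligned strings `a`, `b`, `score`, `identity`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  a <- normalize_sequence(a); b <- normalize_sequence(b)
  r <- cpp_global_align(a, b, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
  list(a = r$a, b = r$b, score = r$score,
       identity = if (r$length > 0) r$matches / r$length else NA_real_)
}

#' Best local alignment by full Smith-Waterman dynamic programming
#'
#' Brute-force affine-gap local alignment over the complete DP matrix.
#' Exact but quadratic: the independent oracle against which the
#' seed-and-extend heuristic of [find_hsps()] is validated on small inputs.
#'
#' @param a,b sequence strings (query, subject).
#' @param scheme a [scoring_scheme()].
#' @return list with `score`, 0-based half-open `qstart`/`qend`/
#'   `sstart`/`send`, `matches`, `length`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  a <- normalize_sequence(a); b <- normalize_sequence(b)
  cpp_local_align(a, b, scheme$match, scheme$mismatch,
                  scheme$gap_open, scheme$gap_extend)
}
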