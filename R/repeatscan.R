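#' Repeat-analysis parameters
#'
#' Defaults follow the field's convention for plant mitogenome repeat scans:
#' word size 7 with an E-value cutoff of 1e-6 (detects repeats down to
#' ~30 bp), size bins 30-100, 101-300, 301-1000 and >1001 bp, and a 1 kb
#' threshold for the "large" repeat class that is collapsed before
#' shared-DNA estimation.
#'
#' @param word_size seed word size.
#' @param evalue_max E-value cutoff.
#' @param min_repeat_len minimal repeat (and shared-DNA hit) length, bp.
#' @param size_bins lower bounds of the size bins, bp.
#' @param large_repeat_min repeats strictly longer than this are "large".
#' @param scheme [scoring_scheme()] in force.
#' @return object of class `RepeatParams`.
#' @export
repeat_params <- function(word_size = 7L, evalue_max = 1e-6,
                          min_repeat_len = 30L,
                          size_bins = c(30L, 101L, 301L, 1001L),
                          large_repeat_min = 1000L,
                          scheme = scoring_scheme()) {
  stopifnot(word_size >= 4, evalue_max > 0, min_repeat_len >= 1,
            !is.unsorted(size_bins))
  structure(list(word_size = as.integer(word_size), evalue_max = evalue_max,
                 min_repeat_len = as.integer(min_repeat_len),
                 size_bins = as.integer(size_bins),
                 large_repeat_min = as.integer(large_repeat_min),
                 scheme = scheme),
            class = "RepeatParams")
}

#' Dispersed repeats by genome self-comparison
#'
#' The genome is used as both query and subject in a seed-and-extend search;
#' the trivial full-length main-diagonal self-hit is removed and all other
#' hits are retained, including reciprocal duplicates (A-vs-B and B-vs-A),
#' so that both copies of every repeat contribute to repetitive coverage.
#'
#' @param g a `Genome`.
#' @param params [repeat_params()].
#' @return `hsp_table` of self-hits.
#' @export
dispersed_repeats <- function(g, params = repeat_params()) {
  find_hsps(g, g, word_size = params$word_size,
            evalue_max = params$evalue_max, scheme = params$scheme,
            min_len = params$min_repeat_len, self = TRUE)
}

#' Tandem repeat arrays
#'
#' A tandem-repeat-finder-style detector: candidate periods are proposed by
#' self-comparison at fixed lags (k-mer recurrence), and each candidate
#' array is verified against its column-majority consensus motif with
#' match +2 / mismatch -7 scoring; arrays scoring at least `min_score` are
#' reported with fractional copy number. Overlapping calls at harmonic
#' periods are deduplicated keeping the highest score, then the smallest
#' period.
#'
#' @param g a `Genome`.
#' @param min_period,max_period period range scanned, bp.
#' @param min_score minimal consensus-alignment score (TRF-like default 50).
#' @param match,mismatch consensus verification scores (positive values;
#'   mismatch is a penalty).
#' @return data.frame with 0-based half-open `start`, `end`, `period`,
#'   `copy_number`, `score`, `motif`.
#' @export
tandem_repeats <- function(g, min_period = 1L, max_period = 500L,
                           min_score = 50L, match = 2L, mismatch = 7L) {
  g <- as_genome(g, "genome")
  cand <- cpp_tandem_scan(g$sequence, as.integer(min_period),
                          as.integer(max_period), as.integer(min_score),
                          as.integer(match), as.integer(mismatch))
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$score, cand$period, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      k <- which(keep)
      ov <- pmin(cand$end[i], cand$end[k]) - pmax(cand$start[i], cand$start[k])
      minlen <- pmin(cand$end[i] - cand$start[i], cand$end[k] - cand$start[k])
      if (any(ov > 0.5 * minlen)) ok <- FALSE
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a genome into repetitive and single-copy DNA
#'
#' Both query- and subject-side intervals of every dispersed self-hit, plus
#' tandem array intervals, are union-merged; partly or wholly overlapping
#' repeats are treated as a single repeat unit. Size-bin counts are reported
#' for merged units (default) and for raw hits.
#'
#' @param g a `Genome`.
#' @param params [repeat_params()].
#' @param dispersed optional precomputed [dispersed_repeats()] table.
#' @param tandem optional precomputed [tandem_repeats()] table.
#' @return object of class `RepeatCatalog`.
#' @export
partition_repeats <- function(g, params = repeat_params(),
                              dispersed = NULL, tandem = NULL) {
  g <- as_genome(g, "genome")
  if (is.null(dispersed)) dispersed <- dispersed_repeats(g, params)
  if (is.null(tandem)) tandem <- tandem_repeats(g)
  iv <- rbind(
    data.frame(start = dispersed$qstart, end = dispersed$qend),
    data.frame(start = dispersed$sstart, end = dispersed$send),
    if (nrow(tandem)) data.frame(start = tandem$start, end = tandem$end))
  merged <- merge_intervals(iv)
  repetitive_bp <- interval_union_length(merged)
  single_copy_bp <- g$length_bp - repetitive_bp
  bins <- params$size_bins
  bin_label <- function(len) {
    lab <- rep(NA_character_, length(len))
    for (i in seq_along(bins)) {
      hi <- if (i < length(bins)) bins[i + 1] - 1L else Inf
      lab[len >= bins[i] & len <= hi] <-
        if (is.finite(hi)) paste0(bins[i], "-", hi) else paste0(">", bins[i] - 1L)
    }
    lab
  }
  unit_len <- if (nrow(merged)) merged$end - merged$start else integer(0)
  hit_len <- dispersed$length
  bin_levels <- bin_label(bins)
  bin_counts <- table(factor(bin_label(unit_len), levels = bin_levels))
  bin_counts_hits <- table(factor(bin_label(hit_len), levels = bin_levels))
  structure(list(
    genome_id = g$id,
    genome_length = g$length_bp,
    dispersed_hits = dispersed,
    tandem_repeats = tandem,
    merged_units = merged,
    repetitive_bp = repetitive_bp,
    repetitive_pct = 100 * repetitive_bp / g$length_bp,
    single_copy_bp = single_copy_bp,
    single_copy_pct = 100 * single_copy_bp / g$length_bp,
    bin_counts = bin_counts,
    bin_counts_hits = bin_counts_hits,
    params = params), class = "RepeatCatalog")
}

#' @export
print.RepeatCatalog <- function(x, ...) {
  cat(sprintf("RepeatCatalog '%s' (%s bp)\n", x$genome_id,
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  repetitive: %.1f%% (%s bp) in %d merged units; single-copy %.1f%%\n",
              x$repetitive_pct, format(x$repetitive_bp, big.mark = ","),
              nrow(x$merged_units), x$single_copy_pct))
  cat(sprintf("  tandem arrays: %d; dispersed hits: %d\n",
              nrow(x$tandem_repeats), nrow(x$dispersed_hits)))
  invisible(x)
}

# single-linkage repeat-family clustering. Nodes are the query- and
# subject-side intervals of the large HSPs; edges join (a) the two sides of
# one HSP ("these locations are copies of each other") and (b) intervals
# overlapping >= 50% reciprocally ("these records are the same location").
cluster_repeat_families <- function(iv, hsp_pairs) {
  n <- nrow(iv)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  link <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  for (k in seq_len(nrow(hsp_pairs))) link(hsp_pairs[k, 1], hsp_pairs[k, 2])
  ir <- IRanges::IRanges(iv$start + 1L, iv$end)
  ov <- IRanges::findOverlaps(ir, ir)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
  recip <- w >= 0.5 * IRanges::width(ir[qi]) & w >= 0.5 * IRanges::width(ir[si])
  for (k in which(recip)) link(qi[k], si[k])
  vapply(seq_len(n), find, integer(1))
}

#' Collapse large repeat families to a single copy
#'
#' Self-hits longer than `large_repeat_min` define the large repeat class;
#' their query- and subject-side intervals are clustered into families by
#' single linkage over >= 50% reciprocal overlap. In each family the
#' leftmost copy is retained and all other copies are deleted (deletion
#' intervals union-merged across families so no base is deleted twice,
#' applied right to left). This prevents multicopy sequence from inflating
#' shared-DNA estimates.
#'
#' @param g a `Genome`.
#' @param catalog optional [partition_repeats()] result for `g`.
#' @param params [repeat_params()].
#' @return object of class `CollapsedGenome`: a `Genome` plus
#'   `deleted_intervals`, `original_length` and `collapsed_len_bp`.
#' @export
collapse_large_repeats <- function(g, catalog = NULL,
                                   params = repeat_params()) {
  g <- as_genome(g, "genome")
  if (is.null(catalog)) {
    disp <- dispersed_repeats(g, params)
    tand <- data.frame(start = integer(0), end = integer(0))
  } else {
    disp <- catalog$dispersed_hits
    tand <- catalog$tandem_repeats
  }
  big <- disp[disp$length > params$large_repeat_min, , drop = FALSE]
  nb <- nrow(big)
  iv <- rbind(data.frame(start = big$qstart, end = big$qend),
              data.frame(start = big$sstart, end = big$send))
  del <- data.frame(start = integer(0), end = integer(0))
  if (nb > 0L) {
    fam <- cluster_repeat_families(iv, cbind(seq_len(nb), nb + seq_len(nb)))
    drop <- do.call(rbind, lapply(split(seq_len(nrow(iv)), fam), function(idx) {
      # collapse near-duplicate records into disjoint copy locations,
      # then keep the leftmost location and delete the others
      locs <- merge_intervals(iv[idx, , drop = FALSE])
      locs[-1L, , drop = FALSE]
    }))
    if (!is.null(drop) && nrow(drop) > 0L) del <- merge_intervals(drop)
  }
  seq <- g$sequence
  if (nrow(del) > 0L) {
    for (i in rev(seq_len(nrow(del)))) {
      seq <- paste0(substr(seq, 1L, del$start[i]),
                    substr(seq, del$end[i] + 1L, nchar(seq)))
    }
  }
  out <- genome(g$id, seq, circular = FALSE)
  structure(c(unclass(out),
              list(deleted_intervals = del,
                   original_length = g$length_bp,
                   collapsed_len_bp = nchar(seq))),
            class = c("CollapsedGenome", "Genome"))
}
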