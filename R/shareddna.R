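#' Shared DNA between two (collapsed) genomes
#'
#' Pairwise comparison with the same seed-and-extend parameters as the
#' repeat analysis; shared DNA is the union length of the query-side
#' intervals of all retained HSPs (query-coverage convention, so the matrix
#' is direction-dependent). Genomes should normally be collapsed with
#' [collapse_large_repeats()] first so multicopy sequence does not inflate
#' the estimate.
#'
#' @param query,subject `Genome` or `CollapsedGenome` objects.
#' @param params [repeat_params()].
#' @return list with `shared_bp`, `shared_pct` (of query length),
#'   `intervals` (query-side, merged) and the raw `hits`.
#' @export
shared_dna <- function(query, subject, params = repeat_params()) {
  q <- as_genome(query, "query"); s <- as_genome(subject, "subject")
  hits <- find_hsps(q, s, word_size = params$word_size,
                    evalue_max = params$evalue_max, scheme = params$scheme,
                    min_len = params$min_repeat_len)
  iv <- merge_intervals(data.frame(start = hits$qstart, end = hits$qend))
  bp <- interval_union_length(iv)
  list(shared_bp = bp, shared_pct = 100 * bp / q$length_bp,
       intervals = iv, hits = hits)
}

#' Pairwise shared-DNA matrix over a genome set
#'
#' @param genomes named list of `Genome` objects (typically collapsed).
#' @param params [repeat_params()].
#' @return object of class `SharedDNAMatrix`: list with `shared_bp` and
#'   `shared_pct` matrices (rows = query, columns = subject; diagonal =
#'   query length / 100%).
#' @export
shared_matrix <- function(genomes, params = repeat_params()) {
  ids <- unname(vapply(genomes, `[[`, character(1), "id"))
  n <- length(genomes)
  bp <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { bp[i, j] <- genomes[[i]]$length_bp; next }
      bp[i, j] <- shared_dna(genomes[[i]], genomes[[j]], params)$shared_bp
    }
  }
  lens <- vapply(genomes, `[[`, numeric(1), "length_bp")
  structure(list(genome_ids = ids, shared_bp = bp,
                 shared_pct = 100 * bp / lens), class = "SharedDNAMatrix")
}

#' Plastid-derived insertions (MIPTs) in a mitogenome
#'
#' The mitogenome is the query against its corresponding plastome; hits of
#' at least `min_len` bp (default 100, shorter putative MIPTs are excluded)
#' are reported with the union length of their mitogenome-side intervals.
#'
#' @param mito,plastome `Genome` objects.
#' @param params [repeat_params()].
#' @param min_len minimal MIPT length, bp.
#' @return object of class `MIPTReport`: list with `mipts` (one row per
#'   hit: mito/plastome intervals, identity), `intervals` (merged,
#'   mito side), `total_bp`, `pct_of_genome`.
#' @export
mipt_scan <- function(mito, plastome, params = repeat_params(),
                      min_len = 100L) {
  m <- as_genome(mito, "mito")
  hits <- find_hsps(m, plastome, word_size = params$word_size,
                    evalue_max = params$evalue_max, scheme = params$scheme,
                    min_len = max(min_len, params$min_repeat_len))
  hits <- hits[hits$length >= min_len, , drop = FALSE]
  iv <- merge_intervals(data.frame(start = hits$qstart, end = hits$qend))
  bp <- interval_union_length(iv)
  structure(list(genome_id = m$id, mipts = hits, intervals = iv,
                 total_bp = bp, pct_of_genome = 100 * bp / m$length_bp),
            class = "MIPTReport")
}

#' Shared-DNA decay against genetic distance
#'
#' For each query genome, subjects are ordered by K2P coding-sequence
#' distance and the association between shared DNA and distance is
#' summarized with Pearson and Spearman correlations; the "half-life"
#' distance at which shared percentage first crosses 50% is linearly
#' interpolated between bracketing points (NA when never crossed).
#'
#' @param shared a `SharedDNAMatrix`.
#' @param dist square K2P distance matrix over the same genome ids.
#' @return data.frame (one row per query) with `pearson_r`, `spearman_rho`,
#'   `half_life_k2p`, `n_subjects`; per-query tables in attribute `tables`.
#' @export
decay_analysis <- function(shared, dist) {
  stopifnot(inherits(shared, "SharedDNAMatrix"))
  ids <- shared$genome_ids
  stopifnot(all(ids %in% rownames(dist)), all(ids %in% colnames(dist)))
  tables <- list()
  res <- lapply(ids, function(q) {
    subj <- setdiff(ids, q)
    tab <- data.frame(subject = subj,
                      k2p = dist[q, subj],
                      shared_bp = shared$shared_bp[q, subj],
                      shared_pct = shared$shared_pct[q, subj],
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$k2p), , drop = FALSE]
    rownames(tab) <- NULL
    tables[[q]] <<- tab
    pe <- sp <- NA_real_
    if (nrow(tab) >= 3 && stats::sd(tab$shared_bp) > 0 && stats::sd(tab$k2p) > 0) {
      pe <- stats::cor(tab$shared_bp, tab$k2p, method = "pearson")
      sp <- stats::cor(tab$shared_bp, tab$k2p, method = "spearman")
    } else if (nrow(tab) >= 3 && stats::sd(tab$shared_bp) == 0) {
      pe <- 0; sp <- 0 # no variance in shared DNA: no decay signal
    }
    hl <- NA_real_
    below <- which(tab$shared_pct < 50)
    if (length(below) && below[1] > 1) {
      i <- below[1]
      x0 <- tab$k2p[i - 1]; x1 <- tab$k2p[i]
      y0 <- tab$shared_pct[i - 1]; y1 <- tab$shared_pct[i]
      hl <- x0 + (50 - y0) * (x1 - x0) / (y1 - y0)
    } else if (length(below) && below[1] == 1) hl <- tab$k2p[1]
    data.frame(query = q, pearson_r = pe, spearman_rho = sp,
               half_life_k2p = hl, n_subjects = nrow(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "tables") <- tables
  out
}

#' Horizontal-transfer donor profile of a query genome
#'
#' Shared DNA of the query (e.g. a concatenated parasite mitogenome)
#' against each subject genome; subjects are ranked and the maximal subject
#' is flagged as the putative donor lineage.
#'
#' @param query a `Genome` (or concatenated multipartite genome).
#' @param subjects list of >= 2 (collapsed) `Genome` objects.
#' @param params [repeat_params()].
#' @return object of class `HGTProfile`: list with `query_id`,
#'   `shared_bp_by_subject` (named, rank order), `table`, `putative_donor`.
#' @export
hgt_profile <- function(query, subjects, params = repeat_params()) {
  if (length(subjects) < 2L) stop("hgt_profile needs >= 2 subjects")
  q <- as_genome(query, "query")
  ids <- unname(vapply(subjects, `[[`, character(1), "id"))
  bp <- vapply(subjects, function(s) shared_dna(q, s, params)$shared_bp,
               numeric(1))
  names(bp) <- ids
  ord <- order(-bp)
  tab <- data.frame(subject = ids[ord], shared_bp = bp[ord],
                    shared_pct = 100 * bp[ord] / q$length_bp,
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(query_id = q$id, shared_bp_by_subject = bp[ord],
                 table = tab, putative_donor = ids[ord][1]),
            class = "HGTProfile")
}

#' @export
print.HGTProfile <- function(x, ...) {
  cat(sprintf("HGTProfile query '%s': putative donor '%s'\n",
              x$query_id, x$putative_donor))
  print(x$table)
  invisible(x)
}

#' Consistency between two HGT profiles
#'
#' Per-subject percentage 100 * a / b over subjects present in both
#' profiles, and their arithmetic mean. Used to compare a parasite-as-query
#' profile with the donor-as-query profile: a consistent ratio indicates
#' the parasite carries that fraction of the donor-lineage mitogenome.
#'
#' @param a,b `HGTProfile` objects (numerator and denominator).
#' @return list with `per_subject` (named percentages) and
#'   `mean_consistency_pct`.
#' @export
profile_consistency <- function(a, b) {
  pa <- a$shared_bp_by_subject; pb <- b$shared_bp_by_subject
  common <- intersect(names(pa), names(pb))
  if (length(common) < 2L) stop("profile_consistency needs >= 2 common subjects")
  zero <- common[pb[common] == 0]
  if (length(zero)) {
    warning("excluding subject(s) with zero denominator: ",
            paste(zero, collapse = ", "))
    common <- setdiff(common, zero)
  }
  pct <- 100 * pa[common] / pb[common]
  list(per_subject = pct, mean_consistency_pct = mean(pct))
}
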