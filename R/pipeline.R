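#' Boxplot statistics with 1.5-IQR outlier rule
#'
#' Quartiles by linear interpolation between order statistics (type 7, the
#' common default); outliers are exactly the values outside
#' `[q1 - 1.5*IQR, q3 + 1.5*IQR]` and whiskers sit at the most extreme
#' non-outlier values. Used to summarize genome-size distributions.
#'
#' @param values numeric vector, length >= 1.
#' @return object of class `BoxStats`: list with `median`, `q1`, `q3`,
#'   `iqr`, `whisker_lo`, `whisker_hi`, `outliers`, `n`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) stop("boxplot_stats: empty input")
  values <- as.numeric(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inliers <- values[values >= lo & values <= hi]
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 whisker_lo = min(inliers), whisker_hi = max(inliers),
                 outliers = sort(out), n = length(values)),
            class = "BoxStats")
}

#' @export
print.BoxStats <- function(x, ...) {
  cat(sprintf("BoxStats (n=%d): median %.4g, IQR [%.4g, %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
              length(x$outliers)))
  invisible(x)
}

param_header <- function(params, extra = NULL) {
  c(sprintf("mitodecay %s", as.character(utils::packageVersion("mitodecay"))),
    sprintf("word_size=%d evalue_max=%g min_repeat_len=%d large_repeat_min=%d",
            params$word_size, params$evalue_max, params$min_repeat_len,
            params$large_repeat_min),
    sprintf("scoring match=%+d mismatch=%+d gap_open=%d gap_extend=%d",
            params$scheme$match, params$scheme$mismatch,
            params$scheme$gap_open, params$scheme$gap_extend),
    extra)
}

#' Run the end-to-end comparative mitogenome pipeline
#'
#' Orchestrates repeat scanning, large-repeat collapsing, pairwise
#' shared-DNA estimation, optional MIPT detection, gene classification /
#' K2P distances and decay analysis over a genome set, writing TSV/BED
#' report tables to `out_dir`. Inputs are either FASTA paths or a
#' simulation config (in which case a truth-comparison appendix is
#' written too). Every report echoes the parameter set in `#` header
#' lines; re-running with an identical config is byte-identical.
#'
#' @param genomes named list of `Genome` objects, or a character vector of
#'   FASTA paths, or `NULL` when `sim` is given.
#' @param sim optional [simulation_config()]; simulated genomes are used.
#' @param plastomes optional named list of plastome `Genome`s (names
#'   matching genome ids) for MIPT scans.
#' @param gene_refs optional named vector of reference CDS per gene for
#'   gene classification and K2P distances.
#' @param params [repeat_params()].
#' @param stages character subset of
#'   `c("repeats","collapse","shared","mipt","genes","decay")`.
#' @param out_dir report directory (created).
#' @return invisibly, a list with the computed objects (`catalogs`,
#'   `collapsed`, `shared`, `k2p`, `decay`, `mipt`, `gene_status`,
#'   `summary`).
#' @export
run_pipeline <- function(genomes = NULL, sim = NULL, plastomes = NULL,
                         gene_refs = NULL, params = repeat_params(),
                         stages = c("repeats", "collapse", "shared",
                                    "mipt", "genes", "decay"),
                         out_dir = "mitodecay_report") {
  if (length(stages) == 0L) stop("no pipeline stages enabled")
  stages <- match.arg(stages, several.ok = TRUE)
  truth <- NULL
  if (!is.null(sim)) {
    simres <- evolve(sim)
    genomes <- simres$genomes
    if (is.null(gene_refs)) gene_refs <- simres$gene_refs
    if (is.null(plastomes)) {
      plastomes <- rep(list(simres$plastome), length(genomes))
      names(plastomes) <- names(genomes)
    }
    truth <- simres$truth
  } else if (is.character(genomes)) {
    genomes <- unlist(lapply(genomes, read_fasta), recursive = FALSE)
    names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  }
  if (is.null(genomes) || length(genomes) == 0L)
    stop("no input genomes (give genomes or a simulation config)")
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) stop("genomes must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- param_header(params)
  res <- list()

  if ("repeats" %in% stages) {
    res$catalogs <- lapply(genomes, partition_repeats, params = params)
    tab <- do.call(rbind, lapply(res$catalogs, function(ct) {
      data.frame(id = ct$genome_id, length_bp = ct$genome_length,
                 repetitive_bp = ct$repetitive_bp,
                 repetitive_pct = round(ct$repetitive_pct, 1),
                 single_copy_bp = ct$single_copy_bp,
                 single_copy_pct = round(ct$single_copy_pct, 1),
                 n_tandem = nrow(ct$tandem_repeats),
                 t(as.matrix(ct$bin_counts)),
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
    f <- file.path(out_dir, "repeats_summary.tsv")
    writeLines(paste0("# ", hdr), f)
    suppressWarnings(utils::write.table(tab, f, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    for (id in ids)
      write_bed(res$catalogs[[id]]$merged_units, id,
                file.path(out_dir, paste0("repeats_", id, ".bed")))
  }

  if ("collapse" %in% stages) {
    res$collapsed <- lapply(ids, function(id)
      collapse_large_repeats(genomes[[id]], catalog = res$catalogs[[id]],
                             params = params))
    names(res$collapsed) <- ids
    write_fasta(res$collapsed, file.path(out_dir, "collapsed_genomes.fasta"))
  }

  if ("shared" %in% stages) {
    gset <- if (!is.null(res$collapsed)) res$collapsed else genomes
    res$shared <- shared_matrix(gset, params)
    write_tsv_matrix(res$shared$shared_bp / 1000,
                     file.path(out_dir, "shared_dna_kb.tsv"),
                     header = c(hdr, "shared DNA (kb), rows=query"))
    write_tsv_matrix(round(res$shared$shared_pct, 2),
                     file.path(out_dir, "shared_dna_pct.tsv"),
                     header = c(hdr, "shared DNA (% of query), rows=query"))
  }

  if ("mipt" %in% stages && !is.null(plastomes)) {
    res$mipt <- lapply(ids[ids %in% names(plastomes)], function(id)
      mipt_scan(genomes[[id]], plastomes[[id]], params))
    names(res$mipt) <- ids[ids %in% names(plastomes)]
    tab <- do.call(rbind, lapply(res$mipt, function(m)
      data.frame(id = m$genome_id, mipt_bp = m$total_bp,
                 mipt_pct = round(m$pct_of_genome, 2),
                 n_mipt = nrow(m$intervals))))
    f <- file.path(out_dir, "mipt_summary.tsv")
    writeLines(paste0("# ", hdr), f)
    suppressWarnings(utils::write.table(tab, f, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }

  if ("genes" %in% stages && !is.null(gene_refs)) {
    models <- lapply(genomes, function(g) {
      ms <- lapply(names(gene_refs), function(gn)
        classify_gene(g, gene_refs[[gn]], gn, params))
      names(ms) <- names(gene_refs)
      ms
    })
    status <- t(vapply(models, function(ms)
      vapply(ms, `[[`, character(1), "status"), character(length(gene_refs))))
    res$gene_status <- status
    utils::write.table(
      data.frame(id = rownames(status), status, check.names = FALSE),
      file.path(out_dir, "gene_content.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    # per-genome spliced gene sequences for K2P (intact genes only)
    gene_seqs <- lapply(ids, function(id) {
      g <- genomes[[id]]
      out <- character(0)
      for (gn in names(gene_refs)) {
        m <- models[[id]][[gn]]
        if (m$status == "intact" && nrow(m$exons) >= 1) {
          seg <- paste(vapply(seq_len(nrow(m$exons)), function(i)
            substr(g$sequence, m$exons$start[i] + 1L, m$exons$end[i]),
            character(1)), collapse = "")
          if (m$strand == "-") seg <- reverse_complement(seg)
          out[gn] <- seg
        }
      }
      out
    })
    names(gene_seqs) <- ids
    res$k2p <- k2p_matrix(gene_seqs, scheme = params$scheme)
    write_tsv_matrix(signif(res$k2p, 6), file.path(out_dir, "k2p_matrix.tsv"),
                     header = c(hdr, "K2P distance, 26-gene-style concatenation, pairwise deletion"))
  }

  if ("decay" %in% stages && !is.null(res$shared) && !is.null(res$k2p)) {
    res$decay <- decay_analysis(res$shared, res$k2p)
    utils::write.table(res$decay, file.path(out_dir, "decay_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # genome-size boxplot statistics (always cheap)
  sizes <- vapply(genomes, `[[`, numeric(1), "length_bp")
  bs <- boxplot_stats(sizes)
  writeLines(c(paste0("# ", hdr),
               sprintf("median\t%g", bs$median), sprintf("q1\t%g", bs$q1),
               sprintf("q3\t%g", bs$q3), sprintf("iqr\t%g", bs$iqr),
               sprintf("whisker_lo\t%g", bs$whisker_lo),
               sprintf("whisker_hi\t%g", bs$whisker_hi),
               sprintf("outliers\t%s", paste(bs$outliers, collapse = ","))),
             file.path(out_dir, "genome_size_boxstats.tsv"))
  res$summary <- bs

  if (!is.null(truth)) {
    res$truth <- truth
    if (!is.null(res$shared)) {
      cmp <- data.frame(
        pair = outer(ids, ids, paste, sep = "-")[upper.tri(diag(length(ids)))],
        measured_bp = res$shared$shared_bp[upper.tri(res$shared$shared_bp)],
        truth_bp = truth$shared_bp[ids, ids][upper.tri(truth$shared_bp)])
      utils::write.table(cmp, file.path(out_dir, "truth_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(res)
}
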