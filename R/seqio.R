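#' Construct a Genome object
#'
#' The unit every analysis stage consumes: a named nucleotide sequence with a
#' topology flag. Sequences are uppercase-normalized over the alphabet
#' \{A,C,G,T,N\}; `U` is mapped to `T`. Plant mitochondrial master chromosomes
#' map as circles, so `circular` defaults to `TRUE`, but all analyses treat
#' the sequence as linear (as deposited).
#'
#' @param id short unique label (first whitespace-delimited FASTA header token).
#' @param sequence nucleotide string; lowercase and `U` are normalized.
#' @param circular logical topology flag.
#' @return an object of class `Genome` with fields `id`, `sequence`,
#'   `length_bp` and `circular`.
#' @export
genome <- function(id, sequence, circular = TRUE) {
  seq <- normalize_sequence(sequence)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("illegal sequence character(s) in genome '", id, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  structure(list(id = as.character(id), sequence = seq,
                 length_bp = nchar(seq), circular = isTRUE(circular)),
            class = "Genome")
}

normalize_sequence <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %s bp (%s)\n", x$id,
              format(x$length_bp, big.mark = ","),
              if (x$circular) "circular, analyzed as linear" else "linear"))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' One `Genome` per record, in file order; ids are the first
#' whitespace-delimited header token. Illegal residues (anything outside
#' A,C,G,T,N after normalization) raise a format error naming the first
#' offending line.
#'
#' @param path FASTA file path.
#' @param circular topology flag applied to every record.
#' @return list of [genome()] objects.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA '", path, "': no records")
  seqs <- normalize_sequence(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    lines <- readLines(path, warn = FALSE)
    is_seq <- !startsWith(lines, ">")
    off <- which(is_seq & grepl("[^ACGTNacgtnUu[:space:]]", lines))[1]
    stop("malformed FASTA '", path, "': illegal sequence character at line ",
         if (is.na(off)) "?" else off)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) warning("duplicate FASTA ids in ", path)
  unname(Map(function(i, s) genome(i, s, circular = circular), ids, seqs))
}

#' Write genomes to a FASTA file
#'
#' @param genomes list of `Genome` objects (a single `Genome` is accepted).
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Length of the set-theoretic union of intervals
#'
#' Intervals are 0-based half-open `[start, end)`; strand-insensitive.
#' Overlapping regions are counted once, matching the convention that
#' overlapping repeat annotations are excluded from double counting.
#'
#' @param intervals data.frame with integer columns `start`, `end`
#'   (0-based half-open), possibly empty.
#' @return total union length in bp (integer).
#' @export
interval_union_length <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0L)
  stopifnot(all(intervals$start < intervals$end), all(intervals$start >= 0))
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Merge overlapping intervals into disjoint units
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @return data.frame of disjoint merged intervals, sorted by `start`.
#' @export
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir)
  data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' Concatenate a multipartite genome set into one record
#'
#' Joins records in input order separated by runs of `N` of length
#' `spacer_len`; an offset table is attached so concatenated coordinates can
#' be mapped back to source records with [map_concat_position()].
#'
#' @param genomes nonempty list of `Genome` objects.
#' @param spacer_len length of the `N` spacer between records.
#' @param id id for the concatenated record.
#' @return a `Genome` with attribute `offsets` (data.frame `id`, `offset`,
#'   `length`).
#' @export
concatenate_multipartite <- function(genomes, spacer_len = 100L,
                                     id = "concatenated") {
  if (length(genomes) == 0L) stop("concatenate_multipartite: empty genome list")
  seqs <- vapply(genomes, `[[`, character(1), "sequence")
  lens <- nchar(seqs)
  offsets <- c(0L, cumsum(lens + spacer_len))[seq_along(seqs)]
  g <- genome(id, paste(seqs, collapse = strrep("N", spacer_len)),
              circular = FALSE)
  attr(g, "offsets") <- data.frame(
    id = vapply(genomes, `[[`, character(1), "id"),
    offset = offsets, length = lens, stringsAsFactors = FALSE)
  g
}

#' Map a concatenated coordinate back to its source record
#'
#' @param concat a `Genome` from [concatenate_multipartite()].
#' @param pos 0-based position(s) in the concatenated sequence.
#' @return data.frame with `id` and local 0-based `pos` (`NA` for positions
#'   falling inside a spacer).
#' @export
map_concat_position <- function(concat, pos) {
  off <- attr(concat, "offsets")
  if (is.null(off)) stop("genome has no concatenation offset table")
  idx <- findInterval(pos, off$offset)
  local <- pos - off$offset[idx]
  in_spacer <- local >= off$length[idx]
  data.frame(id = ifelse(in_spacer, NA_character_, off$id[idx]),
             pos = ifelse(in_spacer, NA_integer_, local),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' Internal 0-based half-open intervals map directly onto BED.
#'
#' @param intervals data.frame with `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param chrom sequence name for column 1.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, chrom, path) {
  n <- nrow(intervals)
  bed <- data.frame(
    chrom = rep(chrom, n),
    start = intervals$start,
    end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else rep(".", n),
    score = if ("score" %in% names(intervals)) intervals$score else rep(0L, n),
    strand = if ("strand" %in% names(intervals)) intervals$strand else rep(".", n))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Matrices carry genome ids as both row and column names (shared-DNA and
#' K2P distance tables). `header` lines are prefixed with `#`.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param header optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         row.names = 1L, check.names = FALSE)
  as.matrix(d)
}
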