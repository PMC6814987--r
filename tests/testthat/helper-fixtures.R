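# deterministic sequence fixtures, built in code at test time

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# insert `seg` after position `at` (0-based) of `bg`
insert_at <- function(bg, at, seg) {
  paste0(substr(bg, 1, at), seg, substr(bg, at + 1, nchar(bg)))
}

# enumerate local alignments above `min_score` by iterated Smith-Waterman
# with query masking: the brute-force oracle for the seeded heuristic
sw_alignments <- function(a, b, scheme = scoring_scheme(),
                          min_score = 1L, max_n = 4L) {
  out <- list()
  for (k in seq_len(max_n)) {
    al <- local_align(a, b, scheme)
    if (al$score < min_score) break
    out[[k]] <- al
    substr(a, al$qstart + 1, al$qend) <-
      strrep("N", al$qend - al$qstart)
  }
  out
}

interval_overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
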