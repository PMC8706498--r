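# Shared builders for in-code fixtures. All randomised helpers take an
# explicit seed so tests are reproducible.

make_meta <- function(ids, groups, taxon = "taxon", locality = "loc") {
  data.frame(sample_id = ids, group = groups,
             taxon_label = taxon, locality = locality,
             stringsAsFactors = FALSE)
}

# Random unambiguous alignment, optionally with some ambiguity/gap symbols.
random_alignment <- function(n, L, seed, locus = "L1",
                             alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1L))
  new_alignment(sprintf("s%02d", seq_len(n)), seqs, locus)
}

# Write a small FASTA (optionally line-wrapped) for I/O tests.
write_fasta_raw <- function(ids, seqs, path, wrap = 0L) {
  con <- file(path, "w")
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    if (wrap > 0L) {
      starts <- seq(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  close(con)
  path
}

# Independent oracle: non-constant columns of the deduplicated alignment,
# by per-column scan over the unique sequences.
oracle_variable_columns <- function(seqs) {
  m <- do.call(rbind, strsplit(unique(seqs), ""))
  which(vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[, j])) > 1L
  }, logical(1L)))
}

# Independent oracle: per-column scan for fixed differences between groups.
oracle_fixed_differences <- function(seqs_a, seqs_b) {
  ma <- do.call(rbind, strsplit(seqs_a, ""))
  mb <- do.call(rbind, strsplit(seqs_b, ""))
  acgt <- c("A", "C", "G", "T")
  keep <- vapply(seq_len(ncol(ma)), function(j) {
    ua <- unique(ma[, j]); ub <- unique(mb[, j])
    length(ua) == 1L && length(ub) == 1L &&
      ua %in% acgt && ub %in% acgt && ua != ub
  }, logical(1L))
  which(keep)
}

# Independent oracle: brute-force double loop over sample pairs using
# p_distance on each pair.
oracle_mean_p_overall <- function(aln) {
  n <- length(aln$seqs)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      vals <- c(vals, p_distance(aln$seqs[i], aln$seqs[j]))
    }
  }
  mean(vals)
}
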