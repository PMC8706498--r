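# Haplotype collapsing, variable-site tables and mitochondrial lineage
# assignment.
#
# A haplotype table is an S3 object of class "hyb_haplotypes":
#   locus     - locus name
#   labels    - haplotype labels, order of first appearance in the input
#   sequences - residue strings named by label
#   members   - list (named by label) of sample ids, input order preserved
#   groups    - owning metadata group per label ("parental_A"/"parental_B"/
#               "query"), NA when built without metadata

#' Collapse aligned sequences into haplotypes
#'
#' Identical residue strings (compared literally, ambiguity codes and gaps
#' included) are grouped into haplotypes. When metadata is supplied, each
#' haplotype is owned by a group — a parental group if any member belongs to
#' it, otherwise `query` — and labelled `<prefix><2-digit counter>` in order
#' of first appearance within that group (e.g. `Ah01`, `Cl01`, `Cl02`). A
#' query sample whose haplotype matches a parental haplotype therefore
#' receives the parental label. `overrides` renames default labels, the
#' supported mechanism for bespoke names of hybrid-only haplotypes.
#'
#' @param aln A `hyb_alignment`.
#' @param meta Optional metadata data.frame (see [read_metadata()]).
#' @param prefixes Named character vector mapping group to label prefix.
#' @param overrides Named character vector: default label -> replacement.
#' @return An object of class `hyb_haplotypes`.
#' @export
collapse_haplotypes <- function(aln, meta = NULL,
                                prefixes = c(parental_A = "Ah",
                                             parental_B = "Cl",
                                             query = "Q"),
                                overrides = character()) {
  stopifnot(inherits(aln, "hyb_alignment"))
  first_idx <- which(!duplicated(aln$seqs))
  hap_seqs <- aln$seqs[first_idx]
  hap_of_sample <- match(aln$seqs, hap_seqs)
  members <- split(aln$ids, factor(hap_of_sample, levels = seq_along(hap_seqs)))
  names(members) <- NULL

  if (is.null(meta)) {
    groups <- rep(NA_character_, length(hap_seqs))
    labels <- sprintf("H%02d", seq_along(hap_seqs))
  } else {
    meta <- validate_metadata(meta)
    unknown <- setdiff(aln$ids, meta$sample_id)
    if (length(unknown)) {
      stop("sample(s) missing from metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    grp <- meta$group[match(aln$ids, meta$sample_id)]
    groups <- vapply(members, function(ids) {
      g <- grp[match(ids, aln$ids)]
      if ("parental_A" %in% g) "parental_A"
      else if ("parental_B" %in% g) "parental_B"
      else "query"
    }, character(1L))
    counter <- c(parental_A = 0L, parental_B = 0L, query = 0L)
    labels <- character(length(hap_seqs))
    for (i in seq_along(hap_seqs)) {
      g <- groups[i]
      counter[g] <- counter[g] + 1L
      labels[i] <- sprintf("%s%02d", prefixes[[g]], counter[g])
    }
  }
  hit <- labels %in% names(overrides)
  labels[hit] <- unname(overrides[labels[hit]])
  if (anyDuplicated(labels)) {
    stop("haplotype labels not unique after overrides", call. = FALSE)
  }
  names(hap_seqs) <- labels
  names(members) <- labels
  names(groups) <- labels
  structure(
    list(locus = aln$locus, labels = labels, sequences = hap_seqs,
         members = members, groups = groups),
    class = "hyb_haplotypes"
  )
}

#' @export
print.hyb_haplotypes <- function(x, ...) {
  cat("<hyb_haplotypes> locus=", x$locus, ": ", length(x$labels),
      " haplotypes\n", sep = "")
  for (l in x$labels) {
    cat("  ", l, " (n=", length(x$members[[l]]), ")\n", sep = "")
  }
  invisible(x)
}

#' Variable-site table of a haplotype table
#'
#' Lists exactly the alignment columns at which the haplotype sequences are
#' not all identical (literal symbol comparison), in ascending position
#' order, with the per-haplotype states read off the sequences. A
#' single-haplotype table yields an empty position list.
#'
#' @param table A `hyb_haplotypes`.
#' @return Object of class `hyb_varsites`: list with `locus`, `positions`
#'   (ascending 1-based integers) and `states` (character matrix, rows =
#'   haplotype labels, columns = positions).
#' @export
variable_sites <- function(table) {
  stopifnot(inherits(table, "hyb_haplotypes"))
  m <- do.call(rbind, strsplit(unname(table$sequences), ""))
  rownames(m) <- table$labels
  var <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  states <- m[, var, drop = FALSE]
  colnames(states) <- var
  structure(
    list(locus = table$locus, positions = as.integer(var), states = states),
    class = "hyb_varsites"
  )
}

#' Write a variable-site table as TSV
#'
#' First column `Taxon/Haplotype`, then one column per variable position.
#'
#' @param vs A `hyb_varsites`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_varsites <- function(vs, path) {
  df <- data.frame(`Taxon/Haplotype` = rownames(vs$states),
                   vs$states, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Hamming distance in sites, pairwise deletion: only columns where both
# symbols are unambiguous non-gap bases are compared. Returns count of
# differing compared sites (and attr "n" = number compared).
hamming_sites <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  if (length(ca) != length(cb)) {
    stop("shape error: sequence lengths differ (", length(ca), " vs ",
         length(cb), ")", call. = FALSE)
  }
  cmp <- is_unambiguous_base(ca) & is_unambiguous_base(cb)
  structure(sum(ca[cmp] != cb[cmp]), n = sum(cmp))
}

#' Assign a query mitochondrial sequence to a parental lineage
#'
#' Computes the Hamming distance (pairwise deletion of gaps and ambiguity
#' codes) from the query to every haplotype of a parental-only haplotype
#' table. The best haplotype is the argmin, ties broken toward the first in
#' table order; the lineage is the owning group of the nearest haplotype;
#' the margin is the absolute difference between the distance to the nearest
#' parental-A haplotype and the nearest parental-B haplotype. A zero margin
#' yields lineage `ambiguous` — maternal direction is never fabricated.
#'
#' @param query Residue string, or a single-sequence `hyb_alignment`.
#' @param parental_table `hyb_haplotypes` built from parental samples only,
#'   with metadata (so each haplotype has an owning parental group).
#' @param sample_id Id recorded in the result (defaults to `"query"`).
#' @return Object of class `hyb_mito_assignment`: list with `sample_id`,
#'   `best_haplotype`, `hamming_to_best`, `lineage`, `margin`, `distances`.
#' @export
assign_mito_lineage <- function(query, parental_table, sample_id = "query") {
  stopifnot(inherits(parental_table, "hyb_haplotypes"))
  if (inherits(query, "hyb_alignment")) {
    stopifnot(length(query$ids) == 1L)
    sample_id <- query$ids[1L]
    query <- query$seqs[1L]
  }
  groups <- parental_table$groups
  if (any(is.na(groups)) || any(groups == "query")) {
    stop("parental_table must be built from parental samples with metadata",
         call. = FALSE)
  }
  d <- vapply(parental_table$sequences, function(s) {
    as.integer(hamming_sites(query, s))
  }, integer(1L))
  best <- which.min(d)  # first minimum in table order
  min_a <- suppressWarnings(min(d[groups == "parental_A"]))
  min_b <- suppressWarnings(min(d[groups == "parental_B"]))
  if (!is.finite(min_a) || !is.finite(min_b)) {
    stop("parental_table must contain both parental lineages", call. = FALSE)
  }
  margin <- abs(min_a - min_b)
  lineage <- if (margin == 0L) "ambiguous"
             else if (min_a < min_b) "parental_A" else "parental_B"
  structure(
    list(sample_id = sample_id,
         best_haplotype = parental_table$labels[best],
         hamming_to_best = unname(d[best]),
         lineage = lineage,
         margin = as.integer(margin),
         distances = d),
    class = "hyb_mito_assignment"
  )
}

#' @export
print.hyb_mito_assignment <- function(x, ...) {
  cat("<mito assignment> ", x$sample_id, ": best=", x$best_haplotype,
      " (d=", x$hamming_to_best, "), lineage=", x$lineage,
      ", margin=", x$margin, "\n", sep = "")
  invisible(x)
}
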