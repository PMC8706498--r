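# Alignment container and file I/O: FASTA alignments, sample metadata TSV,
# locus concatenation with an offset map for position back-translation.
#
# An alignment is an S3 object of class "hyb_alignment":
#   locus   - locus name (string)
#   ids     - sample ids, input order preserved
#   seqs    - uppercase residue strings, parallel to ids
#   length  - number of columns
#   offsets - NULL, or data.frame(locus, start, end) after concatenation
# Coordinates are 1-based and inclusive throughout the package.

SAMPLE_GROUPS <- c("parental_A", "parental_B", "query")

#' Construct an alignment object
#'
#' Validates the alignment invariants: non-empty, unique sample ids, equal
#' residue lengths, and residues restricted to the IUPAC alphabet plus `-`.
#' Residues are case-folded to upper case and `U` is normalised to `T`;
#' `*` and `.` are rejected rather than silently reinterpreted.
#'
#' @param ids Character vector of sample ids.
#' @param seqs Character vector of residue strings, parallel to `ids`.
#' @param locus Locus name.
#' @param offsets Optional per-locus offset map (see [concatenate_loci()]).
#' @return An object of class `hyb_alignment`.
#' @export
new_alignment <- function(ids, seqs, locus, offsets = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("ids and seqs differ in length", call. = FALSE)
  }
  if (length(ids) == 0L) stop("alignment is empty", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (any(lens == 0L)) {
    stop("empty sequence for sample ", ids[which(lens == 0L)[1L]], call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    ref <- lens[1L]
    bad <- which(lens != ref)[1L]
    stop("alignment shape error: record '", ids[bad], "' has ", lens[bad],
         " columns, expected ", ref, call. = FALSE)
  }
  chars <- strsplit(seqs, "")
  for (i in seq_along(chars)) {
    ok <- chars[[i]] %in% ALN_ALPHABET
    if (!all(ok)) {
      pos <- which(!ok)[1L]
      stop("illegal character '", chars[[i]][pos], "' at position ", pos,
           " in record '", ids[i], "'", call. = FALSE)
    }
  }
  structure(
    list(locus = as.character(locus), ids = ids, seqs = seqs,
         length = unname(lens[1L]), offsets = offsets),
    class = "hyb_alignment"
  )
}

#' @export
print.hyb_alignment <- function(x, ...) {
  cat("<hyb_alignment> locus=", x$locus, ": ", length(x$ids),
      " sequences x ", x$length, " columns\n", sep = "")
  invisible(x)
}

# Character matrix view (rows = samples, columns = alignment positions).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

# Rebuild an alignment from a character matrix, keeping row order.
aln_from_matrix <- function(m, locus, offsets = NULL) {
  new_alignment(rownames(m), apply(m, 1L, paste, collapse = ""), locus,
                offsets = offsets)
}

#' Read a pre-aligned FASTA file
#'
#' Records are kept in file order; residues are case-folded to upper and
#' `U` is normalised to `T`. Unequal record lengths or characters outside
#' the IUPAC-plus-gap alphabet are errors naming the offending record.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param locus Locus name to attach to the alignment.
#' @return A `hyb_alignment`.
#' @export
read_alignment <- function(path, locus) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  # FASTA headers may carry descriptions; the id is the first word
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, character(1L), 1L)
  new_alignment(ids, as.character(ss), locus)
}

#' Write an alignment as unwrapped FASTA
#'
#' @param aln A `hyb_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with header columns `sample_id`, `group`, `taxon_label`,
#' `locality`. `group` must be one of `parental_A`, `parental_B`, `query`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("metadata error: cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  validate_metadata(df)
}

# Shared validator so in-memory metadata gets the same checks as files.
validate_metadata <- function(df) {
  need <- c("sample_id", "group", "taxon_label", "locality")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("metadata error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("metadata error: no rows", call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("metadata error: duplicate sample_id ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$group), SAMPLE_GROUPS)
  if (length(bad)) {
    stop("metadata error: unknown group token(s) ",
         paste(sQuote(bad), collapse = ", "), "; allowed: ",
         paste(SAMPLE_GROUPS, collapse = ", "), call. = FALSE)
  }
  df[, need]
}

# Group lookup helper: ids of samples in a metadata group.
group_ids <- function(meta, group) meta$sample_id[meta$group == group]

#' Concatenate locus alignments
#'
#' All alignments must cover the same sample set. Residues are joined in the
#' order the alignments are given; a per-locus offset map (1-based, inclusive
#' start/end columns) is attached for position back-translation.
#'
#' @param alignments List of `hyb_alignment` objects sharing a sample set.
#' @param locus Name for the concatenated alignment.
#' @return A `hyb_alignment` whose `offsets` field is a data.frame with
#'   columns `locus`, `start`, `end`.
#' @export
concatenate_loci <- function(alignments, locus = "concat") {
  stopifnot(length(alignments) >= 1L)
  if (length(alignments) == 1L) return(alignments[[1L]])
  ref_ids <- alignments[[1L]]$ids
  for (a in alignments[-1L]) {
    miss <- setdiff(ref_ids, a$ids)
    extra <- setdiff(a$ids, ref_ids)
    if (length(miss) || length(extra)) {
      stop("concatenation error: locus '", a$locus, "' sample set differs (",
           if (length(miss)) paste("missing:", paste(miss, collapse = ",")),
           if (length(miss) && length(extra)) "; ",
           if (length(extra)) paste("extra:", paste(extra, collapse = ",")),
           ")", call. = FALSE)
    }
  }
  lens <- vapply(alignments, `[[`, numeric(1L), "length")
  ends <- cumsum(lens)
  offsets <- data.frame(
    locus = vapply(alignments, `[[`, character(1L), "locus"),
    start = c(1L, utils::head(ends, -1L) + 1L),
    end = ends,
    stringsAsFactors = FALSE
  )
  seqs <- vapply(ref_ids, function(id) {
    paste(vapply(alignments, function(a) a$seqs[match(id, a$ids)],
                 character(1L)), collapse = "")
  }, character(1L))
  new_alignment(ref_ids, unname(seqs), locus, offsets = offsets)
}

#' Write a locus offset map as TSV
#'
#' @param aln A concatenated `hyb_alignment` carrying an offset map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offsets <- function(aln, path) {
  if (is.null(aln$offsets)) stop("alignment has no offset map", call. = FALSE)
  utils::write.table(aln$offsets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
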