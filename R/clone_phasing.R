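# Phasing of cloned PCR alleles. Molecular cloning isolates single template
# molecules, so each sequenced clone represents one of a heterozygote's two
# alleles; clones of a true hybrid split into two groups matching the two
# parental variants at the diagnostic sites. Assignment uses diagnostic
# sites only — PCR/cloning point errors elsewhere are ignored by design.

#' Construct a clone set
#'
#' @param sample_id Sample the clones were derived from.
#' @param locus Nuclear locus name.
#' @param aln A `hyb_alignment` of the clone sequences (clone ids as sample
#'   ids), pre-aligned to the locus frame.
#' @return Object of class `hyb_clones`.
#' @export
clone_set <- function(sample_id, locus, aln) {
  stopifnot(inherits(aln, "hyb_alignment"))
  structure(list(sample_id = sample_id, locus = locus, aln = aln),
            class = "hyb_clones")
}

#' Read a clone FASTA for one sample and locus
#'
#' The conventional file name is `<sample>_<locus>_clones.fasta`.
#'
#' @param path FASTA path.
#' @param sample_id,locus Identity of the clone set.
#' @return A `hyb_clones`.
#' @export
read_clones <- function(path, sample_id, locus) {
  clone_set(sample_id, locus, read_alignment(path, locus))
}

#' Phase clones into parental allele groups
#'
#' Each clone is assigned to `allele_A` when it carries the parental-A state
#' at a strict majority of the diagnostic sites (symmetrically `allele_B`),
#' and `unassigned` on a tie or when its mismatch fraction against the
#' winning state vector (over diagnostic sites with an unambiguous clone
#' base) exceeds `max_mismatch_fraction`. With two diagnostic sites per
#' locus the default 0.49 degenerates to exact majority.
#'
#' @param clones A `hyb_clones`.
#' @param sites A `hyb_diagsites` for the same locus, non-empty.
#' @param max_mismatch_fraction Tolerated mismatch fraction vs the winning
#'   allele's state vector; default 0.49 (strict majority).
#' @return Object of class `hyb_phasing`: list with `sample_id`, `locus`,
#'   `groups` (named vector clone id -> allele_A/allele_B/unassigned),
#'   `n_groups_observed` (0, 1 or 2), `group_consensus` (named list of
#'   residue strings for the observed groups), `consistent_with_consensus`
#'   (NA until [check_consensus_consistency()] is applied).
#' @export
phase_clones <- function(clones, sites, max_mismatch_fraction = 0.49) {
  stopifnot(inherits(clones, "hyb_clones"), inherits(sites, "hyb_diagsites"))
  st <- sites$sites
  if (nrow(st) == 0L) {
    stop("configuration error: empty diagnostic site set for locus ",
         sites$locus, call. = FALSE)
  }
  m <- aln_matrix(clones$aln)
  if (max(st$position) > ncol(m)) {
    stop("clone alignment shorter than max diagnostic position", call. = FALSE)
  }
  obs <- m[, st$position, drop = FALSE]
  assign_one <- function(row) {
    usable <- is_unambiguous_base(row)
    n_a <- sum(usable & row == st$state_A)
    n_b <- sum(usable & row == st$state_B)
    if (n_a == n_b) return("unassigned")
    win <- if (n_a > n_b) st$state_A else st$state_B
    mism <- sum(usable & row != win) / max(1L, sum(usable))
    if (mism > max_mismatch_fraction) return("unassigned")
    if (n_a > n_b) "allele_A" else "allele_B"
  }
  groups <- apply(obs, 1L, assign_one)
  names(groups) <- clones$aln$ids
  observed <- intersect(c("allele_A", "allele_B"), unique(groups))
  consensus <- lapply(observed, function(g) {
    sub <- m[groups == g, , drop = FALSE]
    cons <- sub[1L, ]
    # majority vote only where the group's clones disagree (point errors)
    disagree <- colSums(sub != matrix(cons, nrow(sub), ncol(sub),
                                      byrow = TRUE)) > 0L
    for (p in which(disagree)) cons[p] <- majority_base(sub[, p])
    paste(cons, collapse = "")
  })
  names(consensus) <- observed
  structure(
    list(sample_id = clones$sample_id, locus = clones$locus,
         groups = groups, n_groups_observed = length(observed),
         group_consensus = consensus,
         consistent_with_consensus = NA),
    class = "hyb_phasing"
  )
}

# Majority symbol of one column; ties broken alphabetically for determinism.
majority_base <- function(col) {
  tab <- sort(table(col), decreasing = TRUE)
  cands <- names(tab)[tab == tab[1L]]
  sort(cands)[1L]
}

#' @export
print.hyb_phasing <- function(x, ...) {
  cat("<phasing> ", x$sample_id, "/", x$locus, ": ",
      sum(x$groups == "allele_A"), " allele_A + ",
      sum(x$groups == "allele_B"), " allele_B + ",
      sum(x$groups == "unassigned"), " unassigned (",
      x$n_groups_observed, " group(s))\n", sep = "")
  invisible(x)
}

#' Check clone phasing against the direct consensus sequence
#'
#' Returns `TRUE` iff at every diagnostic site the IUPAC expansion of the
#' direct (Sanger consensus) symbol equals exactly the set of bases observed
#' across the phased group consensuses at that site — i.e. the dual peaks of
#' the electropherogram are explained by the two recovered alleles.
#'
#' @param phasing A `hyb_phasing` (with at least one observed group).
#' @param consensus Residue string of the sample's direct sequence.
#' @param sites The `hyb_diagsites` used for phasing.
#' @return Logical scalar; also stored in the returned phasing's
#'   `consistent_with_consensus` field via the attribute-updated copy
#'   (assign the result if you want the updated object).
#' @export
check_consensus_consistency <- function(phasing, consensus, sites) {
  stopifnot(inherits(phasing, "hyb_phasing"), inherits(sites, "hyb_diagsites"))
  ch <- strsplit(toupper(consensus), "")[[1L]]
  st <- sites$sites
  if (length(phasing$group_consensus) == 0L) return(FALSE)
  groups <- lapply(phasing$group_consensus, function(s) strsplit(s, "")[[1L]])
  ok <- vapply(seq_len(nrow(st)), function(k) {
    pos <- st$position[k]
    seen <- sort(unique(vapply(groups, `[`, character(1L), pos)))
    sym <- ch[pos]
    if (!sym %in% names(IUPAC_CODES)) return(FALSE)
    identical(iupac_expand(sym), seen)
  }, logical(1L))
  all(ok)
}

#' Write phasing results as TSV
#'
#' One row per clone: sample, locus, clone id, assigned allele group.
#'
#' @param phasings List of `hyb_phasing` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phasing_report <- function(phasings, path) {
  rows <- lapply(phasings, function(p) {
    data.frame(sample_id = p$sample_id, locus = p$locus,
               clone_id = names(p$groups), group = unname(p$groups),
               n_groups_observed = p$n_groups_observed,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(0L), locus = character(0L),
               clone_id = character(0L), group = character(0L),
               n_groups_observed = integer(0L))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
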