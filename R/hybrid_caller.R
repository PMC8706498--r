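# Hybrid verdicts: combine per-locus zygosity profiles with the
# mitochondrial lineage assignment into a categorical classification and a
# maternal-parent inference (mtDNA is maternally inherited, so a hybrid's
# mitochondrial lineage identifies its mother's species).

#' Call a hybrid verdict for one sample
#'
#' Loci with at least one diagnostic site are "informative"; loci without
#' fixed differences are reported but carry no evidence. The sample is
#' `f1_consistent` when, on every informative locus, the fraction of
#' diagnostic sites called `het_AB` is at least `min_het_fraction` and no
#' site is called `other`; `parental_A_like` (`_B_like`) when every
#' informative locus is entirely `hom_A` (`hom_B`); otherwise
#' `inconclusive`. The maternal parent is copied from the mitochondrial
#' lineage only for `f1_consistent` samples and is `not_applicable`
#' otherwise. The label is deliberately "F1-consistent", not "F1": full
#' heterozygosity at a handful of diagnostic sites cannot exclude
#' later-generation hybrids.
#'
#' @param profiles List of `hyb_zygosity` objects (one per locus, all for
#'   the same sample).
#' @param mito A `hyb_mito_assignment` for the same sample, or `NULL` when
#'   no mitochondrial locus was analysed (maternal parent then `ambiguous`
#'   for F1-consistent samples).
#' @param min_het_fraction Minimum het_AB fraction per informative locus in
#'   `(0, 1]`; default 1.0 (every diagnostic site heterozygous).
#' @return Object of class `hyb_verdict`.
#' @export
call_hybrid <- function(profiles, mito = NULL, min_het_fraction = 1.0) {
  if (length(profiles) == 0L) {
    stop("configuration error: empty profile set", call. = FALSE)
  }
  stopifnot(all(vapply(profiles, inherits, logical(1L), "hyb_zygosity")))
  if (min_het_fraction <= 0 || min_het_fraction > 1) {
    stop("min_het_fraction must be in (0, 1]", call. = FALSE)
  }
  ids <- unique(vapply(profiles, `[[`, character(1L), "sample_id"))
  if (length(ids) != 1L) {
    stop("profiles belong to different samples: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  per_locus <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(locus = p$locus, t(p$counts), stringsAsFactors = FALSE)
  }))
  inf <- per_locus$n_sites >= 1L
  informative_loci <- sum(inf)
  classification <- "inconclusive"
  if (informative_loci >= 1L) {
    pl <- per_locus[inf, , drop = FALSE]
    het_ok <- all(pl$n_het_AB / pl$n_sites >= min_het_fraction & pl$n_other == 0L)
    all_a <- all(pl$n_hom_A == pl$n_sites)
    all_b <- all(pl$n_hom_B == pl$n_sites)
    classification <- if (het_ok) "f1_consistent"
                      else if (all_a) "parental_A_like"
                      else if (all_b) "parental_B_like"
                      else "inconclusive"
  }
  maternal <- if (classification == "f1_consistent") {
    if (is.null(mito)) "ambiguous" else mito$lineage
  } else "not_applicable"
  structure(
    list(sample_id = ids, per_locus = per_locus,
         informative_loci = informative_loci,
         mito = mito, classification = classification,
         maternal_parent = maternal,
         min_het_fraction = min_het_fraction),
    class = "hyb_verdict"
  )
}

#' @export
print.hyb_verdict <- function(x, ...) {
  cat("<verdict> ", x$sample_id, ": ", x$classification,
      ", maternal parent = ", x$maternal_parent, "\n", sep = "")
  invisible(x)
}

#' Tabulate hybrid verdicts
#'
#' One row per sample with the classification, per-locus het counts
#' (`<locus>_het` = `n_het_AB/n_sites`), the mitochondrial haplotype and
#' lineage, and the maternal parent. Deterministic column order.
#'
#' @param verdicts List of `hyb_verdict` objects.
#' @return data.frame (zero rows with the full header for empty input).
#' @export
hybrid_report <- function(verdicts) {
  loci <- unique(unlist(lapply(verdicts, function(v) v$per_locus$locus)))
  cols <- c("sample_id", "classification",
            if (length(loci)) paste0(loci, "_het"),
            "informative_loci", "mito_haplotype", "mito_lineage",
            "maternal_parent")
  if (length(verdicts) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0L)), length(cols)),
                                        cols), check.names = FALSE)
    return(df)
  }
  rows <- lapply(verdicts, function(v) {
    row <- list(sample_id = v$sample_id, classification = v$classification)
    for (l in loci) {
      pl <- v$per_locus[v$per_locus$locus == l, , drop = FALSE]
      row[[paste0(l, "_het")]] <- if (nrow(pl)) {
        paste0(pl$n_het_AB[1L], "/", pl$n_sites[1L])
      } else NA_character_
    }
    row$informative_loci <- v$informative_loci
    row$mito_haplotype <- if (is.null(v$mito)) NA_character_ else v$mito$best_haplotype
    row$mito_lineage <- if (is.null(v$mito)) NA_character_ else v$mito$lineage
    row$maternal_parent <- v$maternal_parent
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the hybrid report as TSV
#'
#' @param verdicts List of `hyb_verdict` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hybrid_report <- function(verdicts, path) {
  utils::write.table(hybrid_report(verdicts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
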