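# End-to-end analysis: haplotype structure, diagnostic sites, zygosity,
# mitochondrial assignment, distances, verdicts and clone phasing, as one
# R-level entry point shared by the CLI and the tests.

#' Run the full hybrid-diagnosis analysis
#'
#' @param alignments Named list of `hyb_alignment`, one per locus
#'   (direct/consensus sequences for every sample).
#' @param meta Metadata data.frame covering every sample.
#' @param mito_locus Name of the mitochondrial locus in `alignments`.
#' @param clones Optional list of `hyb_clones` (cloned alleles of query
#'   samples at nuclear loci).
#' @param min_het_fraction Passed to [call_hybrid()].
#' @param max_mismatch_fraction Passed to [phase_clones()].
#' @param bootstrap_reps,seed Passed to [mean_p_distance()] for the
#'   mitochondrial distance report (reps 0 skips the bootstrap SE).
#' @param prefixes,label_overrides Passed to [collapse_haplotypes()].
#' @return List of class `hyb_run` with elements `haplotypes` (per locus),
#'   `varsites` (per locus), `parental_mito_table`, `mito_assignments`,
#'   `diagnostics` (per locus), `profiles`, `distances`,
#'   `verdicts`, `phasings`, `consistency`, `config`.
#' @export
run_hybrid_analysis <- function(alignments, meta, mito_locus,
                                clones = list(),
                                min_het_fraction = 1.0,
                                max_mismatch_fraction = 0.49,
                                bootstrap_reps = 0L, seed = NULL,
                                prefixes = c(parental_A = "Ah",
                                             parental_B = "Cl",
                                             query = "Q"),
                                label_overrides = character()) {
  meta <- validate_metadata(meta)
  if (!mito_locus %in% names(alignments)) {
    stop("mitochondrial locus '", mito_locus, "' not among alignments (",
         paste(names(alignments), collapse = ", "), ")", call. = FALSE)
  }
  nuclear <- setdiff(names(alignments), mito_locus)
  query_ids <- group_ids(meta, "query")
  parental_ids <- c(group_ids(meta, "parental_A"), group_ids(meta, "parental_B"))

  haplotypes <- lapply(alignments, collapse_haplotypes, meta = meta,
                       prefixes = prefixes, overrides = label_overrides)
  varsites <- lapply(haplotypes, function(h) {
    if (length(h$labels) >= 2L) variable_sites(h) else NULL
  })

  # parental-only mitochondrial haplotype table for lineage assignment
  mito_aln <- alignments[[mito_locus]]
  keep <- mito_aln$ids %in% parental_ids
  parental_mito <- collapse_haplotypes(
    new_alignment(mito_aln$ids[keep], mito_aln$seqs[keep], mito_locus),
    meta = meta, prefixes = prefixes, overrides = label_overrides)
  mito_assignments <- lapply(query_ids, function(q) {
    i <- match(q, mito_aln$ids)
    if (is.na(i)) stop("query ", q, " absent from mitochondrial alignment",
                       call. = FALSE)
    assign_mito_lineage(mito_aln$seqs[i], parental_mito, sample_id = q)
  })
  names(mito_assignments) <- query_ids

  # fixed differences on every locus (the mitochondrial ones are reported
  # too); zygosity profiles below use the nuclear loci only
  diagnostics <- lapply(names(alignments), function(l) {
    find_fixed_differences(alignments[[l]], meta)
  })
  names(diagnostics) <- names(alignments)

  profiles <- lapply(query_ids, function(q) {
    lapply(nuclear, function(l) {
      a <- alignments[[l]]
      i <- match(q, a$ids)
      if (is.na(i)) stop("query ", q, " absent from locus ", l, call. = FALSE)
      zygosity_profile(a$seqs[i], diagnostics[[l]], sample_id = q)
    })
  })
  names(profiles) <- query_ids

  distances <- list(
    overall = mean_p_distance(mito_aln, "overall",
                              bootstrap_reps = bootstrap_reps, seed = seed),
    between_groups = mean_p_distance(mito_aln, "between_groups", meta = meta,
                                     bootstrap_reps = bootstrap_reps,
                                     seed = seed)
  )

  verdicts <- lapply(query_ids, function(q) {
    call_hybrid(profiles[[q]], mito_assignments[[q]],
                min_het_fraction = min_het_fraction)
  })
  names(verdicts) <- query_ids

  phasings <- list()
  consistency <- list()
  for (cs in clones) {
    sites <- diagnostics[[cs$locus]]
    if (is.null(sites) || nrow(sites$sites) == 0L) next  # uninformative locus
    ph <- phase_clones(cs, sites, max_mismatch_fraction = max_mismatch_fraction)
    a <- alignments[[cs$locus]]
    i <- match(cs$sample_id, a$ids)
    ph$consistent_with_consensus <- if (!is.na(i)) {
      check_consensus_consistency(ph, a$seqs[i], sites)
    } else NA
    key <- paste(cs$sample_id, cs$locus, sep = "_")
    phasings[[key]] <- ph
    consistency[[key]] <- ph$consistent_with_consensus
  }

  structure(
    list(haplotypes = haplotypes, varsites = varsites,
         parental_mito_table = parental_mito,
         mito_assignments = mito_assignments,
         diagnostics = diagnostics, profiles = profiles,
         distances = distances, verdicts = verdicts,
         phasings = phasings, consistency = consistency,
         config = list(mito_locus = mito_locus,
                       min_het_fraction = min_het_fraction,
                       max_mismatch_fraction = max_mismatch_fraction,
                       bootstrap_reps = bootstrap_reps,
                       seed = if (is.null(seed)) NA else seed)),
    class = "hyb_run"
  )
}

#' @export
print.hyb_run <- function(x, ...) {
  cat("<hyb_run> ", length(x$haplotypes), " loci, ",
      length(x$verdicts), " query sample(s)\n", sep = "")
  for (v in x$verdicts) print(v)
  invisible(x)
}

#' Write all reports of a pipeline run to a directory
#'
#' Each report starts with a `# config:` provenance line echoing the
#' resolved run configuration.
#'
#' @param run A `hyb_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  stopifnot(inherits(run, "hyb_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- paste0("# config: ", jsonlite::toJSON(run$config, auto_unbox = TRUE))
  put <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(cfg, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (l in names(run$haplotypes)) {
    h <- run$haplotypes[[l]]
    put(data.frame(label = h$labels,
                   n_members = vapply(h$members, length, integer(1L)),
                   members = vapply(h$members, paste, character(1L),
                                    collapse = ","),
                   stringsAsFactors = FALSE),
        paste0("haplotypes_", l, ".tsv"))
    vs <- run$varsites[[l]]
    if (!is.null(vs)) {
      put(data.frame(`Taxon/Haplotype` = rownames(vs$states), vs$states,
                     check.names = FALSE, stringsAsFactors = FALSE),
          paste0("varsites_", l, ".tsv"))
    }
  }
  for (l in names(run$diagnostics)) {
    d <- run$diagnostics[[l]]
    put(cbind(locus = rep(d$locus, nrow(d$sites)), d$sites),
        paste0("diagnostics_", l, ".tsv"))
  }
  put(do.call(rbind, lapply(run$mito_assignments, function(m) {
    data.frame(sample_id = m$sample_id, best_haplotype = m$best_haplotype,
               hamming_to_best = m$hamming_to_best, lineage = m$lineage,
               margin = m$margin, stringsAsFactors = FALSE)
  })), "mito_assignments.tsv")
  put(do.call(rbind, lapply(run$distances, function(x) {
    data.frame(mode = x$mode, mean_p_percent = format_percent(x$mean_p),
               se_p_percent = if (is.na(x$se_p)) "NA" else format_percent(x$se_p),
               n_pairs = x$n_pairs, bootstrap_reps = x$bootstrap_reps,
               seed = x$seed, stringsAsFactors = FALSE)
  })), "distances.tsv")
  put(hybrid_report(unname(run$verdicts)), "hybrid_report.tsv")
  if (length(run$phasings)) {
    rows <- do.call(rbind, lapply(run$phasings, function(p) {
      data.frame(sample_id = p$sample_id, locus = p$locus,
                 clone_id = names(p$groups), group = unname(p$groups),
                 n_groups_observed = p$n_groups_observed,
                 consistent_with_consensus = p$consistent_with_consensus,
                 stringsAsFactors = FALSE)
    }))
    put(rows, "phasing_report.tsv")
  }
  invisible(dir)
}
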