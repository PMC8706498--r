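# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes — two lineages separated by a handful of fixed
# substitutions per locus, low within-lineage haplotype diversity with one
# common haplotype and rare singletons, F1 hybrids whose nuclear consensus
# carries two-base ambiguity codes at the diagnostic sites and whose
# mitochondrial haplotype comes from the maternal lineage, and cloned
# allele sequences per nuclear gene — plus full ground truth, so every
# downstream stage can be scored exactly. No mutation-model realism is
# attempted (no ts/tv bias, no rate heterogeneity): the generator targets
# the analysis's assumptions, not evolutionary history.

#' Default locus set for simulations
#'
#' One 658 bp mitochondrial fragment with 4 fixed interlineage differences
#' and 2 extra segregating sites in lineage B (giving B three haplotypes:
#' one common plus two singletons), and three nuclear fragments of 403, 610
#' and 445 bp with 2, 0 and 2 fixed differences and no within-lineage
#' polymorphism.
#'
#' @return List of per-locus parameter lists (`name`, `length`,
#'   `n_fixed_diffs`, `within_polymorphism` = named counts of extra
#'   haplotype-defining segregating sites per lineage, `is_mito`).
#' @export
default_loci <- function() {
  list(
    list(name = "COI", length = 658L, n_fixed_diffs = 4L,
         within_polymorphism = c(parental_A = 0L, parental_B = 2L),
         is_mito = TRUE),
    list(name = "Wingless", length = 403L, n_fixed_diffs = 2L,
         within_polymorphism = c(parental_A = 0L, parental_B = 0L),
         is_mito = FALSE),
    list(name = "RPS5", length = 610L, n_fixed_diffs = 0L,
         within_polymorphism = c(parental_A = 0L, parental_B = 0L),
         is_mito = FALSE),
    list(name = "CaATPase", length = 445L, n_fixed_diffs = 2L,
         within_polymorphism = c(parental_A = 0L, parental_B = 0L),
         is_mito = FALSE)
  )
}

#' Simulation parameters
#'
#' Defaults mirror the study design the generator emulates: 12 parental-A,
#' 15 parental-B and 3 hybrid samples, maternal lineage B, 10 clones per
#' nuclear gene per hybrid, zero clone error.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param loci Per-locus parameters, as [default_loci()].
#' @param n_parental_A,n_parental_B,n_hybrids Sample counts.
#' @param maternal_lineage `"parental_A"`, `"parental_B"` or `"mixed"`
#'   (per-hybrid coin flip).
#' @param n_clones_per_gene Clones sequenced per nuclear gene per hybrid.
#' @param clone_error_rate Per-site error probability in clone sequences.
#' @return Validated list of class `hyb_sim_params`.
#' @export
sim_params <- function(seed = 1L, loci = default_loci(),
                       n_parental_A = 12L, n_parental_B = 15L,
                       n_hybrids = 3L,
                       maternal_lineage = "parental_B",
                       n_clones_per_gene = 10L,
                       clone_error_rate = 0) {
  stopifnot(length(loci) >= 1L)
  if (!maternal_lineage %in% c("parental_A", "parental_B", "mixed")) {
    stop("parameter error: maternal_lineage must be parental_A, parental_B ",
         "or mixed", call. = FALSE)
  }
  n_mito <- sum(vapply(loci, `[[`, logical(1L), "is_mito"))
  if (n_mito != 1L) {
    stop("parameter error: exactly one mitochondrial locus required, got ",
         n_mito, call. = FALSE)
  }
  for (l in loci) {
    budget <- l$n_fixed_diffs + sum(l$within_polymorphism)
    if (budget > l$length) {
      stop("parameter error: locus ", l$name, " needs ", budget,
           " distinct sites but is only ", l$length, " bp", call. = FALSE)
    }
    if (l$n_fixed_diffs < 0L) stop("parameter error: negative n_fixed_diffs",
                                   call. = FALSE)
  }
  if (n_parental_A < 1L || n_parental_B < 1L || n_hybrids < 0L) {
    stop("parameter error: need >= 1 sample per parental lineage", call. = FALSE)
  }
  if (clone_error_rate < 0 || clone_error_rate > 1) {
    stop("parameter error: clone_error_rate outside [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), loci = loci,
         n_parental_A = as.integer(n_parental_A),
         n_parental_B = as.integer(n_parental_B),
         n_hybrids = as.integer(n_hybrids),
         maternal_lineage = maternal_lineage,
         n_clones_per_gene = as.integer(n_clones_per_gene),
         clone_error_rate = clone_error_rate),
    class = "hyb_sim_params"
  )
}

# Stable 31-bit string hash (polynomial rolling hash, modular arithmetic to
# stay inside integer range). Used to derive per-locus substreams so adding
# a locus does not perturb the draws of the others.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

# Sub-seed for a named stream under a master seed; always in [0, 2^31).
substream_seed <- function(seed, name) {
  as.integer((as.numeric(seed) * 2654435761 + stable_hash(name)) %% 2147483647)
}

BASES <- c("A", "C", "G", "T")

# Mutate: pick a base different from `from` using the current RNG stream.
mutate_base <- function(from) sample(setdiff(BASES, from), 1L)

#' Simulate a two-lineage hybrid dataset with ground truth
#'
#' See the package vignette for the generative model. All randomness
#' derives from `params$seed`; per-locus substreams are obtained by stable
#' hashing of the locus name.
#'
#' @param params A `hyb_sim_params`.
#' @return List of class `hyb_simulation` with elements
#'   `alignments` (named list of `hyb_alignment`, direct/consensus
#'   sequences for every sample), `metadata` (data.frame), `clones` (list
#'   of `hyb_clones`, one per hybrid x nuclear locus), and `truth` (list:
#'   `classes`, `maternal`, `diagnostics`, `hybrid_alleles`,
#'   `clone_alleles`, `haplotypes`).
#' @export
simulate_hybrid_data <- function(params) {
  stopifnot(inherits(params, "hyb_sim_params"))
  ids_a <- sprintf("A%02d", seq_len(params$n_parental_A))
  ids_b <- sprintf("B%02d", seq_len(params$n_parental_B))
  ids_h <- if (params$n_hybrids > 0L) sprintf("H%02d", seq_len(params$n_hybrids))
           else character(0L)
  all_ids <- c(ids_a, ids_b, ids_h)

  metadata <- data.frame(
    sample_id = all_ids,
    group = c(rep("parental_A", length(ids_a)),
              rep("parental_B", length(ids_b)),
              rep("query", length(ids_h))),
    taxon_label = c(rep("lineage_A", length(ids_a)),
                    rep("lineage_B", length(ids_b)),
                    rep("putative_hybrid", length(ids_h))),
    locality = "synthetic",
    stringsAsFactors = FALSE
  )

  # maternal lineage per hybrid, drawn on its own substream
  set.seed(substream_seed(params$seed, "maternal"))
  maternal <- switch(params$maternal_lineage,
    parental_A = rep("parental_A", params$n_hybrids),
    parental_B = rep("parental_B", params$n_hybrids),
    mixed = sample(c("parental_A", "parental_B"), params$n_hybrids,
                   replace = TRUE))
  names(maternal) <- ids_h

  alignments <- list()
  clones <- list()
  truth <- list(
    classes = stats::setNames(
      c(rep("parental_A", length(ids_a)), rep("parental_B", length(ids_b)),
        rep("hybrid", length(ids_h))), all_ids),
    maternal = maternal,
    diagnostics = list(), hybrid_alleles = list(), clone_alleles = list(),
    haplotypes = list()
  )

  for (loc in params$loci) {
    set.seed(substream_seed(params$seed, loc$name))
    L <- loc$length
    ancestral <- sample(BASES, L, replace = TRUE)

    n_sites <- loc$n_fixed_diffs + sum(loc$within_polymorphism)
    site_pool <- if (n_sites > 0L) sample.int(L, n_sites) else integer(0L)
    fixed_pos <- sort(utils::head(site_pool, loc$n_fixed_diffs))
    poly_pool <- utils::tail(site_pool, sum(loc$within_polymorphism))

    base_a <- ancestral
    base_b <- ancestral
    state_a <- character(0L); state_b <- character(0L)
    for (p in fixed_pos) {
      base_b[p] <- mutate_base(base_b[p])
      state_a <- c(state_a, base_a[p]); state_b <- c(state_b, base_b[p])
    }
    truth$diagnostics[[loc$name]] <- data.frame(
      position = fixed_pos, state_A = state_a, state_B = state_b,
      stringsAsFactors = FALSE)

    # within-lineage haplotypes: one common haplotype per lineage plus one
    # rare singleton per polymorphic site (skewed frequencies, emulating a
    # dominant haplotype with rare variants)
    lineage_haps <- list()
    pool_idx <- 0L
    for (lin in c("parental_A", "parental_B")) {
      common <- if (lin == "parental_A") base_a else base_b
      haps <- list(common)
      k <- loc$within_polymorphism[[lin]]
      if (length(k) == 0L || is.na(k)) k <- 0L
      for (i in seq_len(k)) {
        pool_idx <- pool_idx + 1L
        p <- poly_pool[pool_idx]
        rare <- common
        rare[p] <- mutate_base(rare[p])
        haps[[i + 1L]] <- rare
      }
      lineage_haps[[lin]] <- haps
    }
    truth$haplotypes[[loc$name]] <- lapply(lineage_haps, function(hs) {
      vapply(hs, paste, character(1L), collapse = "")
    })

    # assign parental samples: rare haplotypes to distinct random samples,
    # everyone else carries the common haplotype
    assign_lineage <- function(ids, haps) {
      hap_idx <- rep(1L, length(ids))
      n_rare <- length(haps) - 1L
      if (n_rare > 0L) {
        carriers <- sample(seq_along(ids), min(n_rare, length(ids)))
        hap_idx[carriers] <- 1L + seq_along(carriers)
      }
      vapply(hap_idx, function(i) paste(haps[[i]], collapse = ""), character(1L))
    }
    seq_a <- assign_lineage(ids_a, lineage_haps$parental_A)
    seq_b <- assign_lineage(ids_b, lineage_haps$parental_B)

    # hybrids: one allele per lineage (nuclear), maternal haplotype (mito)
    seq_h <- character(length(ids_h))
    for (i in seq_along(ids_h)) {
      hid <- ids_h[i]
      if (loc$is_mito) {
        haps <- lineage_haps[[maternal[[hid]]]]
        seq_h[i] <- paste(haps[[sample.int(length(haps), 1L)]], collapse = "")
      } else {
        al_a <- lineage_haps$parental_A[[sample.int(length(lineage_haps$parental_A), 1L)]]
        al_b <- lineage_haps$parental_B[[sample.int(length(lineage_haps$parental_B), 1L)]]
        cons <- vapply(seq_len(L), function(p) {
          if (al_a[p] == al_b[p]) al_a[p] else iupac_code(c(al_a[p], al_b[p]))
        }, character(1L))
        seq_h[i] <- paste(cons, collapse = "")
        truth$hybrid_alleles[[hid]][[loc$name]] <- c(
          allele_A = paste(al_a, collapse = ""),
          allele_B = paste(al_b, collapse = ""))
        # clones for this hybrid/locus on their own substream
        set.seed(substream_seed(params$seed,
                                paste(loc$name, hid, "clones", sep = "/")))
        n_cl <- params$n_clones_per_gene
        origin <- sample(c("A", "B"), n_cl, replace = TRUE)
        clone_seqs <- vapply(origin, function(o) {
          tmpl <- if (o == "A") al_a else al_b
          if (params$clone_error_rate > 0) {
            err <- stats::runif(L) < params$clone_error_rate
            for (p in which(err)) tmpl[p] <- mutate_base(tmpl[p])
          }
          paste(tmpl, collapse = "")
        }, character(1L), USE.NAMES = FALSE)
        clone_ids <- sprintf("%s_%s_cl%02d", hid, loc$name, seq_len(n_cl))
        truth$clone_alleles[[hid]][[loc$name]] <-
          stats::setNames(origin, clone_ids)
        clones[[paste(hid, loc$name, sep = "_")]] <- clone_set(
          hid, loc$name, new_alignment(clone_ids, clone_seqs, loc$name))
        # back to the locus stream is unnecessary: clones are generated
        # last for this hybrid before the next independent draw
        set.seed(substream_seed(params$seed,
                                paste(loc$name, hid, "resume", sep = "/")))
      }
    }
    alignments[[loc$name]] <- new_alignment(
      all_ids, c(seq_a, seq_b, seq_h), loc$name)
  }

  structure(
    list(alignments = alignments, metadata = metadata, clones = clones,
         truth = truth, params = params),
    class = "hyb_simulation"
  )
}

#' @export
print.hyb_simulation <- function(x, ...) {
  cat("<hyb_simulation> seed=", x$params$seed, ": ",
      length(x$alignments), " loci, ",
      nrow(x$metadata), " samples (",
      x$params$n_hybrids, " hybrids), ",
      length(x$clones), " clone sets\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Materialises one FASTA per locus, `metadata.tsv`,
#' `clones/<sample>_<locus>_clones.fasta` and `truth.json`.
#'
#' @param sim A `hyb_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "hyb_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(sim$alignments)) {
    write_alignment(sim$alignments[[name]], file.path(dir, paste0(name, ".fasta")))
  }
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sim$clones)) {
    dir.create(file.path(dir, "clones"), showWarnings = FALSE)
    for (cs in sim$clones) {
      write_alignment(cs$aln, file.path(
        dir, "clones", paste0(cs$sample_id, "_", cs$locus, "_clones.fasta")))
    }
  }
  # named atomic vectors serialise as bare arrays; convert to lists so the
  # sample/clone names survive the JSON round trip
  truth <- sim$truth
  truth$classes <- as.list(truth$classes)
  truth$maternal <- as.list(truth$maternal)
  truth$hybrid_alleles <- lapply(truth$hybrid_alleles,
                                 function(x) lapply(x, as.list))
  truth$clone_alleles <- lapply(truth$clone_alleles,
                                function(x) lapply(x, as.list))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Score pipeline outputs against simulation ground truth
#'
#' @param verdicts List of `hyb_verdict` for the simulated query samples.
#' @param phasings List of `hyb_phasing` for the simulated clone sets
#'   (may be empty).
#' @param truth The `truth` element of a `hyb_simulation`.
#' @param diagnostics Optional named list (by locus) of `hyb_diagsites`
#'   discovered by the pipeline, scored for site precision/recall.
#' @return List with `classification` (data.frame sample/true/called/
#'   correct), `classification_accuracy`, `maternal_accuracy`,
#'   `clone_accuracy`, and (when `diagnostics` given) `site_precision`,
#'   `site_recall`.
#' @export
score_against_truth <- function(verdicts, phasings, truth,
                                diagnostics = NULL) {
  v_ids <- vapply(verdicts, `[[`, character(1L), "sample_id")
  unknown <- setdiff(v_ids, names(truth$classes))
  if (length(unknown)) {
    stop("scoring error: sample id(s) not in truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cls <- data.frame(
    sample_id = v_ids,
    true_class = unname(truth$classes[v_ids]),
    called = vapply(verdicts, `[[`, character(1L), "classification"),
    stringsAsFactors = FALSE
  )
  cls$correct <- (cls$true_class == "hybrid" & cls$called == "f1_consistent") |
    (cls$true_class == "parental_A" & cls$called == "parental_A_like") |
    (cls$true_class == "parental_B" & cls$called == "parental_B_like")
  hyb <- cls$true_class == "hybrid"
  maternal_calls <- vapply(verdicts, `[[`, character(1L), "maternal_parent")
  mat_ok <- maternal_calls[hyb] == unname(truth$maternal[v_ids[hyb]])

  clone_acc <- NA_real_
  if (length(phasings)) {
    correct <- 0L; total <- 0L
    for (p in phasings) {
      tr <- truth$clone_alleles[[p$sample_id]][[p$locus]]
      if (is.null(tr)) {
        stop("scoring error: no clone truth for ", p$sample_id, "/", p$locus,
             call. = FALSE)
      }
      tr <- tr[names(p$groups)]
      if (anyNA(tr)) stop("scoring error: clone id mismatch for ",
                          p$sample_id, "/", p$locus, call. = FALSE)
      correct <- correct + sum(paste0("allele_", tr) == p$groups)
      total <- total + length(tr)
    }
    clone_acc <- correct / total
  }

  out <- list(
    classification = cls,
    classification_accuracy = mean(cls$correct),
    maternal_accuracy = if (any(hyb)) mean(mat_ok) else NA_real_,
    clone_accuracy = clone_acc
  )
  if (!is.null(diagnostics)) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (loc in names(truth$diagnostics)) {
      true_pos <- truth$diagnostics[[loc]]$position
      found <- if (!is.null(diagnostics[[loc]])) {
        diagnostics[[loc]]$sites$position
      } else integer(0L)
      tp <- tp + length(intersect(found, true_pos))
      fp <- fp + length(setdiff(found, true_pos))
      fn <- fn + length(setdiff(true_pos, found))
    }
    out$site_precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    out$site_recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  }
  out
}
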