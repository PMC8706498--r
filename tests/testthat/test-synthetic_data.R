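small_loci <- function(mito_fixed = 2L, nuc_fixed = 2L,
                       wpA = 0L, wpB = 0L) {
  list(
    list(name = "COI", length = 80L, n_fixed_diffs = mito_fixed,
         within_polymorphism = c(parental_A = wpA, parental_B = wpB),
         is_mito = TRUE),
    list(name = "Wg", length = 60L, n_fixed_diffs = nuc_fixed,
         within_polymorphism = c(parental_A = 0L, parental_B = 0L),
         is_mito = FALSE))
}

test_that("sim_params validates its invariants", {
  expect_s3_class(sim_params(), "hyb_sim_params")
  expect_error(sim_params(loci = list(small_loci()[[2]])), "mitochondrial")
  expect_error(sim_params(loci = c(small_loci(), small_loci()[1])),
               "exactly one mitochondrial")
  too_big <- small_loci(); too_big[[2]]$n_fixed_diffs <- 100L
  expect_error(sim_params(loci = too_big), "parameter error")
  expect_error(sim_params(maternal_lineage = "mother"), "maternal_lineage")
  expect_error(sim_params(clone_error_rate = 1.5), "clone_error_rate")
})

test_that("same seed gives byte-identical datasets, different seeds differ", {
  p <- sim_params(seed = 11, loci = small_loci())
  s1 <- simulate_hybrid_data(p)
  s2 <- simulate_hybrid_data(p)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$clones, `[[`, "aln"),
                   lapply(s2$clones, `[[`, "aln"))
  s3 <- simulate_hybrid_data(sim_params(seed = 12, loci = small_loci()))
  expect_false(identical(s1$alignments, s3$alignments))

  # written datasets are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("per-locus substreams: adding a locus does not perturb the others", {
  base <- simulate_hybrid_data(sim_params(seed = 5, loci = small_loci()))
  extended <- small_loci()
  extended[[3]] <- list(name = "Extra", length = 40L, n_fixed_diffs = 1L,
                        within_polymorphism = c(parental_A = 0L,
                                                parental_B = 0L),
                        is_mito = FALSE)
  ext <- simulate_hybrid_data(sim_params(seed = 5, loci = extended))
  expect_identical(base$alignments$COI$seqs, ext$alignments$COI$seqs)
  expect_identical(base$truth$diagnostics$Wg, ext$truth$diagnostics$Wg)
})

test_that("hybrid consensus carries ambiguity codes exactly at allele differences", {
  sim <- simulate_hybrid_data(sim_params(seed = 3))
  for (hid in c("H01", "H02", "H03")) {
    wg <- sim$alignments$Wingless
    cons <- wg$seqs[match(hid, wg$ids)]
    het <- detect_het_sites(cons)
    # default generator: 2 fixed differences, no within-lineage variation,
    # so exactly the 2 diagnostic positions are heterozygous
    expect_equal(het$position, sim$truth$diagnostics$Wingless$position)
    rp <- sim$alignments$RPS5
    expect_equal(nrow(detect_het_sites(rp$seqs[match(hid, rp$ids)])), 0L)
  }

  # no hybrids -> no ambiguity codes anywhere
  clean <- simulate_hybrid_data(sim_params(seed = 4, n_hybrids = 0,
                                           loci = small_loci()))
  for (aln in clean$alignments) {
    expect_false(any(grepl("[RYSWKMBDHVN]", aln$seqs)))
  }
  expect_length(clean$clones, 0L)
})

test_that("mitochondrial haplotypes of hybrids come from the maternal lineage", {
  for (lin in c("parental_A", "parental_B")) {
    sim <- simulate_hybrid_data(sim_params(seed = 8, maternal_lineage = lin,
                                           loci = small_loci(wpB = 2L)))
    mito <- sim$alignments$COI
    for (hid in names(sim$truth$maternal)) {
      hseq <- mito$seqs[match(hid, mito$ids)]
      expect_true(hseq %in% sim$truth$haplotypes$COI[[lin]])
    }
  }
})

test_that("planted diagnostic sites are recovered exactly (200 seeds)", {
  for (seed in 1:200) {
    sim <- simulate_hybrid_data(sim_params(
      seed = seed, n_parental_A = 3, n_parental_B = 3, n_hybrids = 0,
      loci = small_loci(mito_fixed = 3L, nuc_fixed = 2L)))
    for (loc in c("COI", "Wg")) {
      got <- find_fixed_differences(sim$alignments[[loc]], sim$metadata)$sites
      expect_equal(got, sim$truth$diagnostics[[loc]])
    }
  }
})

test_that("within-lineage polymorphism at a site destroys fixedness there", {
  # lineage B segregates at 2 extra sites; with every B sample present the
  # polymorphic sites must never be reported as fixed differences
  for (seed in 1:50) {
    sim <- simulate_hybrid_data(sim_params(
      seed = seed, n_parental_A = 3, n_parental_B = 6, n_hybrids = 0,
      loci = small_loci(wpB = 2L)))
    got <- find_fixed_differences(sim$alignments$COI, sim$metadata)$sites
    expect_equal(got, sim$truth$diagnostics$COI)
    # the two B-polymorphic sites are variable among B samples, hence absent
    b_seqs <- sim$alignments$COI$seqs[sim$metadata$group == "parental_B"]
    poly <- oracle_variable_columns(b_seqs)
    expect_false(any(poly %in% got$position))
  }
})

test_that("haplotype frequencies are skewed: one common haplotype plus singletons", {
  sim <- simulate_hybrid_data(sim_params(seed = 21, n_hybrids = 0,
                                         loci = small_loci(wpB = 2L)))
  b_ids <- sim$metadata$sample_id[sim$metadata$group == "parental_B"]
  keep <- sim$alignments$COI$ids %in% b_ids
  hb <- collapse_haplotypes(new_alignment(sim$alignments$COI$ids[keep],
                                          sim$alignments$COI$seqs[keep],
                                          "COI"))
  counts <- sort(vapply(hb$members, length, integer(1)))
  expect_equal(unname(counts), c(1L, 1L, 13L))
})

test_that("score_against_truth is exact on a clean run and strict on ids", {
  sim <- simulate_hybrid_data(sim_params(seed = 31))
  run <- run_hybrid_analysis(sim$alignments, sim$metadata, "COI",
                             clones = sim$clones)
  sc <- score_against_truth(unname(run$verdicts), unname(run$phasings),
                            sim$truth, diagnostics = run$diagnostics)
  expect_equal(sc$classification_accuracy, 1)
  expect_equal(sc$maternal_accuracy, 1)
  expect_equal(sc$clone_accuracy, 1)
  expect_equal(sc$site_precision, 1)
  expect_equal(sc$site_recall, 1)
  expect_true(all(vapply(run$verdicts, `[[`, character(1),
                         "maternal_parent") == "parental_B"))

  bad_truth <- sim$truth
  names(bad_truth$classes) <- paste0("X", names(bad_truth$classes))
  expect_error(score_against_truth(unname(run$verdicts), list(), bad_truth),
               "scoring error")
})
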