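fx <- fixture_table2_coi()

test_that("find_fixed_differences recovers the four fixed mitochondrial sites", {
  d <- find_fixed_differences(fx$alignment, fx$metadata)
  expect_equal(d$sites$position, c(40L, 103L, 271L, 361L))
  expect_equal(d$sites$state_A, c("G", "T", "A", "C"))
  expect_equal(d$sites$state_B, c("A", "C", "T", "T"))
})

test_that("fixedness is absolute and order-invariant", {
  aln <- fx$alignment
  meta <- fx$metadata
  ref <- find_fixed_differences(aln, meta)$sites

  # permuting sample order changes nothing
  set.seed(5)
  perm <- sample(length(aln$ids))
  shuffled <- new_alignment(aln$ids[perm], aln$seqs[perm], aln$locus)
  expect_equal(find_fixed_differences(shuffled, meta)$sites, ref)

  # duplicating a parental sample changes nothing
  dup <- new_alignment(c(aln$ids, "06FRbis"),
                       c(aln$seqs, aln$seqs[match("06FR", aln$ids)]),
                       aln$locus)
  meta_dup <- rbind(meta, make_meta("06FRbis", "parental_A"))
  expect_equal(find_fixed_differences(dup, meta_dup)$sites, ref)

  # one discordant parental base removes the site (no frequency threshold)
  m <- strsplit(aln$seqs[match("06FR", aln$ids)], "")[[1]]
  m[40] <- "A"  # parental_A sample carrying the B state at site 40
  disc <- new_alignment(c(aln$ids, "06FRvar"),
                        c(aln$seqs, paste(m, collapse = "")), aln$locus)
  meta_disc <- rbind(meta, make_meta("06FRvar", "parental_A"))
  expect_equal(find_fixed_differences(disc, meta_disc)$sites$position,
               c(103L, 271L, 361L))

  # an ambiguity code inside a parental group disqualifies the site too
  m2 <- strsplit(aln$seqs[match("06FR", aln$ids)], "")[[1]]
  m2[103] <- "Y"
  amb <- new_alignment(c(aln$ids, "06FRamb"),
                       c(aln$seqs, paste(m2, collapse = "")), aln$locus)
  meta_amb <- rbind(meta, make_meta("06FRamb", "parental_A"))
  expect_equal(find_fixed_differences(amb, meta_amb)$sites$position,
               c(40L, 271L, 361L))
})

test_that("find_fixed_differences edge cases", {
  # minimal case: single-column difference
  aln <- new_alignment(c("a", "b"), c("AAAA", "AAAT"), "x")
  meta <- make_meta(c("a", "b"), c("parental_A", "parental_B"))
  d <- find_fixed_differences(aln, meta)
  expect_equal(d$sites,
               data.frame(position = 4L, state_A = "A", state_B = "T"))

  # shared polymorphism with no fixed split -> empty set
  aln2 <- new_alignment(c("a1", "a2", "b1", "b2"),
                        c("ACGT", "ACGA", "ACGT", "ACGA"), "x")
  meta2 <- make_meta(c("a1", "a2", "b1", "b2"),
                     c("parental_A", "parental_A", "parental_B", "parental_B"))
  expect_equal(nrow(find_fixed_differences(aln2, meta2)$sites), 0L)

  # empty parental group is a configuration error
  meta3 <- make_meta(c("a", "b"), c("parental_A", "query"))
  expect_error(find_fixed_differences(aln, meta3), "configuration error")
})

test_that("find_fixed_differences equals the brute-force oracle on random data", {
  for (seed in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1); L <- sample(10:60, 1)
    aln <- random_alignment(na + nb, L, seed = 300 + seed,
                            alphabet = c("A", "C", "G", "T", "R", "N", "-"))
    meta <- make_meta(aln$ids, c(rep("parental_A", na), rep("parental_B", nb)))
    got <- find_fixed_differences(aln, meta)$sites$position
    expect_equal(got, oracle_fixed_differences(aln$seqs[1:na],
                                               aln$seqs[(na + 1):(na + nb)]))
  }
})

test_that("detect_het_sites finds exactly the multi-base IUPAC symbols", {
  hits <- detect_het_sites("ACRT")
  expect_equal(hits$position, 3L)
  expect_equal(hits$symbol, "R")
  expect_equal(hits$expansion, "A/G")

  expect_equal(nrow(detect_het_sites("ACGTACGT")), 0L)
  # N is a no-call by default, counted only on request; gaps never count
  expect_equal(nrow(detect_het_sites("ACNT-A")), 0L)
  expect_equal(detect_het_sites("ACNT-A", include_n = TRUE)$position, 3L)
  expect_equal(detect_het_sites("aywrskmbdhvn")$position, 2:11)
})

test_that("zygosity_profile calls hom/het/other per diagnostic site", {
  sites <- structure(list(locus = "x", sites = data.frame(
    position = c(2L, 5L), state_A = c("A", "C"), state_B = c("G", "T"),
    stringsAsFactors = FALSE)), class = "hyb_diagsites")

  hom_b <- zygosity_profile("TGCAT", sites, "q1")
  expect_equal(hom_b$calls$call, c("hom_B", "hom_B"))

  het <- zygosity_profile("TRCAY", sites, "q2")
  expect_equal(het$calls$call, c("het_AB", "het_AB"))
  expect_equal(unname(het$counts["n_het_AB"]), 2L)

  # N, gap, an unrelated base, or an ambiguity code not equal to {A,B}
  # are all "other"
  other <- zygosity_profile("TNCAC", sites, "q3")
  expect_equal(other$calls$call, c("other", "hom_A"))
  # M={A,C} != {A,G} and K={G,T} != {C,T}: near-miss ambiguity is "other"
  wrongamb <- zygosity_profile("TMCAK", sites, "q4")
  expect_equal(wrongamb$calls$call, c("other", "other"))
  expect_error(zygosity_profile("TG", sites), "shorter")
})

test_that("p_distance matches hand counts on fixture haplotypes", {
  vs <- variable_sites(collapse_haplotypes(fx$alignment, fx$metadata,
                                           overrides = fx$label_overrides))
  seq_of <- function(id) fx$alignment$seqs[match(id, fx$alignment$ids)]
  # Ah01 (06FR) vs Cl01 (01RUB): the 4 fixed sites over 658 columns
  expect_equal(p_distance(seq_of("06FR"), seq_of("01RUB")), 4 / 658)
  # Ah01 vs Cl03 (19RUB): 7 differing variable columns
  expect_equal(p_distance(seq_of("06FR"), seq_of("19RUB")), 7 / 658)
  expect_equal(p_distance(seq_of("01RUB"), seq_of("01RUB")), 0)

  # pairwise deletion shrinks the denominator
  expect_equal(p_distance("ACGT", "ACGA"), 1 / 4)
  expect_equal(p_distance("ACG-", "ACGA"), 0 / 3)
  expect_equal(p_distance("RCGT", "ACGA"), 1 / 3)
  expect_error(p_distance("RR--", "AAAA"), "undefined distance")
})

test_that("mean_p_distance overall equals the brute-force double loop", {
  # fixture value, and the printed one-decimal percentage
  mp <- mean_p_distance(fx$alignment, "overall")
  expect_equal(mp$mean_p, oracle_mean_p_overall(fx$alignment))
  expect_equal(mp$mean_p, (1090 / 435) / 658)
  expect_equal(round(100 * mp$mean_p, 1), 0.4)
  expect_equal(mp$n_pairs, 435L)

  # random instances incl. ambiguity codes
  for (seed in 1:8) {
    aln <- random_alignment(sample(2:8, 1), sample(8:40, 1), seed = 700 + seed,
                            alphabet = c("A", "C", "G", "T", "Y", "-"))
    got <- tryCatch(mean_p_distance(aln, "overall")$mean_p, error = identity)
    exp <- tryCatch(oracle_mean_p_overall(aln), error = identity)
    if (inherits(exp, "error")) expect_s3_class(got, "error")
    else expect_equal(got, exp)
  }

  # a 2-sample alignment reduces to the pair distance
  two <- new_alignment(c("a", "b"), c("ACGTAC", "ACGTAT"), "x")
  expect_equal(mean_p_distance(two, "overall")$mean_p,
               p_distance("ACGTAC", "ACGTAT"))
})

test_that("between-groups mode averages parental A x B pairs", {
  bg <- mean_p_distance(fx$alignment, "between_groups", meta = fx$metadata)
  expect_equal(bg$n_pairs, 12L * 15L)
  # every A x B pair differs by the 4 fixed sites plus the B-haplotype
  # private sites; hand-weighted mean over multiplicities 13/1/1:
  # 12*13 pairs at 4/658, 12*1 at 5/658 (Cl02), 12*1 at 7/658 (Cl03)
  expect_equal(bg$mean_p, (12 * 13 * 4 + 12 * 5 + 12 * 7) / (180 * 658))
  expect_error(mean_p_distance(fx$alignment, "between_groups"), "metadata")
})

test_that("bootstrap SE is seeded, reproducible, and vanishes for identical data", {
  a <- mean_p_distance(fx$alignment, "overall", bootstrap_reps = 200, seed = 9)
  b <- mean_p_distance(fx$alignment, "overall", bootstrap_reps = 200, seed = 9)
  expect_identical(a$se_p, b$se_p)
  expect_gt(a$se_p, 0)
  c2 <- mean_p_distance(fx$alignment, "overall", bootstrap_reps = 200, seed = 10)
  expect_false(identical(a$se_p, c2$se_p))

  same <- new_alignment(c("a", "b", "c"), rep("ACGTACGT", 3), "x")
  s <- mean_p_distance(same, "overall", bootstrap_reps = 50, seed = 1)
  expect_equal(s$mean_p, 0)
  expect_equal(s$se_p, 0)
  expect_error(mean_p_distance(fx$alignment, "overall", bootstrap_reps = 10),
               "seed")
})
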