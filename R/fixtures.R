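# Packaged reference fixtures, built programmatically (text-only, no
# downloads). The mitochondrial fixture reconstructs the published
# variable-site table of the 658 bp COI barcode fragment exactly: the nine
# variable columns carry the printed states of the five haplotypes, every
# other column is an arbitrary-but-fixed constant base, and the 30
# specimens are assigned haplotypes per the published haplotype-to-specimen
# account. The nuclear loci of the full fixture are synthetic stand-ins:
# the real GenBank sequences are not reproducible from the printed tables,
# so only their lengths and diagnostic-site positions are mirrored.

# Variable COI columns and haplotype states (published variable-site table).
COI_VARIABLE_POSITIONS <- c(40L, 82L, 103L, 271L, 310L, 361L, 400L, 406L, 529L)
COI_HAPLOTYPE_STATES <- rbind(
  Ah01   = c("G", "T", "T", "A", "A", "C", "T", "T", "C"),
  Cl01   = c("A", "T", "C", "T", "A", "T", "T", "T", "C"),
  Cl02   = c("A", "T", "C", "T", "G", "T", "T", "T", "C"),
  Cl03   = c("A", "C", "C", "T", "A", "T", "C", "T", "A"),
  AhCl01 = c("A", "T", "C", "T", "A", "T", "T", "C", "C")
)
colnames(COI_HAPLOTYPE_STATES) <- COI_VARIABLE_POSITIONS

COI_LENGTH <- 658L

# 30 specimens: id, group, taxon label, locality, COI haplotype. Record
# order: parental-B first (so within-group label numbering reproduces
# Cl01/Cl02/Cl03 in first-appearance order), then parental-A, then the
# three putative hybrids.
coi_specimens <- function() {
  rub <- data.frame(
    sample_id = c("01RUB", "02RUB", "03RUB", "04RUB", "05RUB",
                  "15RUB", "16RUB", "17RUB", "18RUB", "19RUB",
                  "28RUB", "29RUB", "30RUB", "31RUB", "32RUB"),
    group = "parental_B", taxon_label = "Callophrys rubi",
    locality = c(rep("Irkutsk", 5L), rep("Buryatia", 5L), rep("Omsk", 5L)),
    haplotype = "Cl01", stringsAsFactors = FALSE)
  rub$haplotype[rub$sample_id == "05RUB"] <- "Cl02"  # Irkutsk singleton
  rub$haplotype[rub$sample_id == "19RUB"] <- "Cl03"  # Buryatia singleton
  fr <- data.frame(
    sample_id = c("06FR", "07FR", "08FR", "10FR",
                  "20FR", "21FR", "22FR", "23FR", "24FR",
                  "25FR", "26FR", "27FR"),
    group = "parental_A", taxon_label = "Ahlbergia frivaldszkyi",
    locality = c(rep("Irkutsk", 4L), rep("Buryatia", 5L), rep("Omsk", 3L)),
    haplotype = "Ah01", stringsAsFactors = FALSE)
  cfr <- data.frame(
    sample_id = c("CFR01", "CFR02", "CFR03"),
    group = "query", taxon_label = "putative hybrid",
    locality = c("Irkutsk", "Buryatia", "Omsk"),
    haplotype = c("Cl01", "Cl03", "AhCl01"), stringsAsFactors = FALSE)
  rbind(rub, fr, cfr)
}

# Full-length haplotype sequences: fixed filler pattern, published states
# at the variable columns.
coi_haplotype_seqs <- function() {
  filler <- rep(c("A", "C", "G", "T"), length.out = COI_LENGTH)
  out <- apply(COI_HAPLOTYPE_STATES, 1L, function(states) {
    s <- filler
    s[COI_VARIABLE_POSITIONS] <- states
    paste(s, collapse = "")
  })
  out
}

#' The packaged 30-specimen COI fixture
#'
#' A 658-column mitochondrial alignment of 12 parental-A, 15 parental-B and
#' 3 query specimens whose variable columns reproduce the published
#' variable-site table (positions 40, 82, 103, 271, 310, 361, 400, 406,
#' 529) and whose haplotype multiplicities are Ah01:12, Cl01:14, Cl02:1,
#' Cl03:2, AhCl01:1. Constant columns are an arbitrary fixed pattern, so
#' every statistic that depends only on variable columns and multiplicities
#' (fixed differences, Hamming distances, p-distances) is exact.
#'
#' @return List with `alignment` (`hyb_alignment`), `metadata` (data.frame)
#'   and `label_overrides` (the override needed to name the hybrid-only
#'   haplotype `AhCl01`).
#' @export
fixture_table2_coi <- function() {
  spec <- coi_specimens()
  haps <- coi_haplotype_seqs()
  aln <- new_alignment(spec$sample_id, unname(haps[spec$haplotype]), "COI")
  meta <- data.frame(sample_id = spec$sample_id, group = spec$group,
                     taxon_label = spec$taxon_label,
                     locality = spec$locality, stringsAsFactors = FALSE)
  list(alignment = aln, metadata = meta,
       label_overrides = c(Q01 = "AhCl01"))
}

# Synthetic nuclear stand-in: lineages identical except at `positions`,
# where A carries state_A and B carries state_B; hybrids get the two-base
# IUPAC code. Filler is a fixed repeating pattern per locus.
nuclear_standin <- function(locus, length, positions, state_A, state_B,
                            spec) {
  filler <- rep(c("G", "A", "T", "C"), length.out = length)
  a <- filler; a[positions] <- state_A
  b <- filler; b[positions] <- state_B
  h <- filler
  for (k in seq_along(positions)) {
    h[positions[k]] <- iupac_code(c(state_A[k], state_B[k]))
  }
  seq_of <- function(group) {
    switch(group, parental_A = a, parental_B = b, query = h)
  }
  seqs <- vapply(spec$group, function(g) paste(seq_of(g), collapse = ""),
                 character(1L), USE.NAMES = FALSE)
  list(
    alignment = new_alignment(spec$sample_id, seqs, locus),
    allele_A = paste(a, collapse = ""),
    allele_B = paste(b, collapse = "")
  )
}

#' The full paper-style fixture: COI plus nuclear stand-ins
#'
#' Extends [fixture_table2_coi()] with three synthetic nuclear loci
#' mirroring the published fragment lengths and diagnostic positions: a
#' 403 bp locus with fixed differences at positions 213 and 271, a 610 bp
#' locus with none, and a 445 bp locus with fixed differences at 151 and
#' 334. Query consensus sequences are heterozygous (two-base IUPAC codes)
#' at every diagnostic site; ten clones per informative nuclear gene per
#' query sample are included, split 5/5 between the two alleles with no
#' clone error. Nucleotide states at the diagnostic sites (and all filler)
#' are synthetic: only positions, lengths and the zygosity structure follow
#' the published analysis.
#'
#' @return List with `alignments` (named list: COI, Wingless, RPS5,
#'   CaATPase), `metadata`, `clones` (list of `hyb_clones`) and
#'   `label_overrides`.
#' @export
fixture_paper_full <- function() {
  base <- fixture_table2_coi()
  spec <- coi_specimens()
  wg <- nuclear_standin("Wingless", 403L, c(213L, 271L),
                        c("C", "G"), c("T", "A"), spec)
  rp <- nuclear_standin("RPS5", 610L, integer(0L),
                        character(0L), character(0L), spec)
  ca <- nuclear_standin("CaATPase", 445L, c(151L, 334L),
                        c("T", "A"), c("C", "G"), spec)
  queries <- spec$sample_id[spec$group == "query"]
  clones <- list()
  for (q in queries) {
    for (loc in list(wg, ca)) {
      name <- loc$alignment$locus
      n <- 10L
      origin <- rep(c("A", "B"), length.out = n)  # 5/5 split, no error
      seqs <- ifelse(origin == "A", loc$allele_A, loc$allele_B)
      ids <- sprintf("%s_%s_cl%02d", q, name, seq_len(n))
      clones[[paste(q, name, sep = "_")]] <-
        clone_set(q, name, new_alignment(ids, seqs, name))
    }
  }
  list(
    alignments = list(COI = base$alignment, Wingless = wg$alignment,
                      RPS5 = rp$alignment, CaATPase = ca$alignment),
    metadata = base$metadata,
    clones = clones,
    label_overrides = base$label_overrides
  )
}

#' Materialise a packaged fixture into a directory
#'
#' @param name `"table2_coi"` or `"paper_full"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(name, dir) {
  if (!name %in% c("table2_coi", "paper_full")) {
    stop("unknown fixture '", name, "'; available: table2_coi, paper_full",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "table2_coi") {
    fx <- fixture_table2_coi()
    write_alignment(fx$alignment, file.path(dir, "COI.fasta"))
    utils::write.table(fx$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    fx <- fixture_paper_full()
    for (nm in names(fx$alignments)) {
      write_alignment(fx$alignments[[nm]], file.path(dir, paste0(nm, ".fasta")))
    }
    utils::write.table(fx$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dir.create(file.path(dir, "clones"), showWarnings = FALSE)
    for (cs in fx$clones) {
      write_alignment(cs$aln, file.path(
        dir, "clones", paste0(cs$sample_id, "_", cs$locus, "_clones.fasta")))
    }
  }
  invisible(dir)
}
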