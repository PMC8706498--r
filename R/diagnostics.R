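# Fixed interspecific differences, heterozygous-site detection, zygosity
# profiles at diagnostic sites, and uncorrected p-distances with a column
# bootstrap standard error.

#' Find fixed differences between the two parental groups
#'
#' A diagnostic site is an alignment column that is monomorphic for an
#' unambiguous base within each parental group and carries a different base
#' in the two groups. Any ambiguity code or gap inside a parental group
#' disqualifies the column; fixedness is absolute (no frequency threshold).
#' Query samples are excluded from the scan.
#'
#' @param aln A `hyb_alignment`.
#' @param meta Metadata data.frame labelling samples `parental_A`,
#'   `parental_B` or `query`.
#' @return Object of class `hyb_diagsites`: list with `locus` and `sites`,
#'   a data.frame with columns `position`, `state_A`, `state_B` in ascending
#'   position order (zero rows when no fixed difference exists).
#' @export
find_fixed_differences <- function(aln, meta) {
  stopifnot(inherits(aln, "hyb_alignment"))
  meta <- validate_metadata(meta)
  m <- aln_matrix(aln)
  ids_a <- intersect(aln$ids, group_ids(meta, "parental_A"))
  ids_b <- intersect(aln$ids, group_ids(meta, "parental_B"))
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop("configuration error: both parental groups must be non-empty ",
         "in the alignment", call. = FALSE)
  }
  ma <- m[ids_a, , drop = FALSE]
  mb <- m[ids_b, , drop = FALSE]
  fixed_state <- function(col) {
    u <- unique(col)
    if (length(u) == 1L && is_unambiguous_base(u)) u else NA_character_
  }
  sa <- apply(ma, 2L, fixed_state)
  sb <- apply(mb, 2L, fixed_state)
  keep <- !is.na(sa) & !is.na(sb) & sa != sb
  structure(
    list(locus = aln$locus,
         sites = data.frame(position = which(keep),
                            state_A = unname(sa[keep]),
                            state_B = unname(sb[keep]),
                            stringsAsFactors = FALSE)),
    class = "hyb_diagsites"
  )
}

#' @export
print.hyb_diagsites <- function(x, ...) {
  cat("<diagnostic sites> locus=", x$locus, ": ", nrow(x$sites),
      " fixed difference(s)\n", sep = "")
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Write diagnostic sites as TSV
#'
#' @param sites A `hyb_diagsites`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagsites <- function(sites, path) {
  df <- cbind(locus = rep(sites$locus, nrow(sites$sites)), sites$sites)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect heterozygous (ambiguity-coded) sites in a sequence
#'
#' Returns every position carrying a 2-, 3- or 4-base IUPAC symbol. In
#' Sanger consensus sequences a two-base code marks a heterozygous position
#' seen as dual electropherogram peaks. `N` is excluded by default as a
#' no-call rather than an observed heterozygote.
#'
#' @param seq Residue string.
#' @param include_n Count `N` as a heterozygous site? Default `FALSE`.
#' @return data.frame with columns `position`, `symbol`, `expansion`
#'   (bases joined with `/`).
#' @export
detect_het_sites <- function(seq, include_n = FALSE) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  amb <- is_ambiguity_code(ch)
  if (!include_n) amb <- amb & ch != "N"
  pos <- which(amb)
  data.frame(
    position = pos,
    symbol = ch[pos],
    expansion = vapply(ch[pos], function(s) {
      paste(iupac_expand(s), collapse = "/")
    }, character(1L), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Zygosity profile of a sequence at diagnostic sites
#'
#' Each diagnostic position is called `hom_A` (symbol equals the parental-A
#' state), `hom_B`, `het_AB` (the symbol's IUPAC expansion equals exactly
#' the two parental states, e.g. `R` for A/G), or `other` for anything else
#' including `N` and gaps.
#'
#' @param seq Residue string (direct/consensus sequence of one sample).
#' @param sites A `hyb_diagsites` for the same locus.
#' @param sample_id Sample id recorded in the profile.
#' @return Object of class `hyb_zygosity`: list with `sample_id`, `locus`,
#'   `calls` (data.frame position/symbol/call) and `counts` (named vector
#'   n_sites, n_het_AB, n_hom_A, n_hom_B, n_other).
#' @export
zygosity_profile <- function(seq, sites, sample_id = "query") {
  stopifnot(inherits(sites, "hyb_diagsites"))
  ch <- strsplit(toupper(seq), "")[[1L]]
  st <- sites$sites
  if (nrow(st) > 0L && max(st$position) > length(ch)) {
    stop("sequence shorter than max diagnostic position", call. = FALSE)
  }
  call_one <- function(sym, a, b) {
    if (sym == a) return("hom_A")
    if (sym == b) return("hom_B")
    if (is_ambiguity_code(sym) &&
        identical(iupac_expand(sym), sort(c(a, b)))) return("het_AB")
    "other"
  }
  calls <- if (nrow(st)) {
    mapply(call_one, ch[st$position], st$state_A, st$state_B)
  } else character(0L)
  counts <- c(
    n_sites = nrow(st),
    n_het_AB = sum(calls == "het_AB"),
    n_hom_A = sum(calls == "hom_A"),
    n_hom_B = sum(calls == "hom_B"),
    n_other = sum(calls == "other")
  )
  structure(
    list(sample_id = sample_id, locus = sites$locus,
         calls = data.frame(position = st$position,
                            symbol = if (nrow(st)) ch[st$position] else character(0L),
                            call = unname(calls),
                            stringsAsFactors = FALSE),
         counts = counts),
    class = "hyb_zygosity"
  )
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of compared sites at which the sequences differ, with
#' pairwise deletion: columns where either symbol is a gap or an ambiguity
#' code are dropped from numerator and denominator. With no gaps or
#' ambiguities the denominator is the alignment length.
#'
#' @param a,b Residue strings of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  h <- hamming_sites(toupper(a), toupper(b))
  n <- attr(h, "n")
  if (n == 0L) stop("undefined distance: zero comparable sites", call. = FALSE)
  as.numeric(h) / n
}

#' Mean pairwise p-distance with bootstrap standard error
#'
#' `mode = "overall"` averages the p-distance over all unordered sample
#' pairs; `mode = "between_groups"` averages over parental-A x parental-B
#' pairs only (metadata required). The standard error is estimated by
#' resampling alignment columns with replacement `bootstrap_reps` times and
#' taking the standard deviation of the recomputed means; the seed makes it
#' bit-reproducible.
#'
#' @param aln A `hyb_alignment` with at least two sequences.
#' @param mode `"overall"` or `"between_groups"`.
#' @param meta Metadata, required for `between_groups`.
#' @param bootstrap_reps Number of bootstrap replicates (0 skips the SE).
#' @param seed Integer seed for the bootstrap (required when reps > 0).
#' @return Object of class `hyb_distance`: list with `mean_p`, `se_p`,
#'   `mode`, `n_pairs`, `bootstrap_reps`, `seed`.
#' @export
mean_p_distance <- function(aln, mode = c("overall", "between_groups"),
                            meta = NULL, bootstrap_reps = 0L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "hyb_alignment"))
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (mode == "overall") {
    if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
    pairs <- utils::combn(n, 2L)
  } else {
    if (is.null(meta)) stop("between_groups mode requires metadata", call. = FALSE)
    meta <- validate_metadata(meta)
    ia <- match(intersect(aln$ids, group_ids(meta, "parental_A")), aln$ids)
    ib <- match(intersect(aln$ids, group_ids(meta, "parental_B")), aln$ids)
    if (length(ia) == 0L || length(ib) == 0L) {
      stop("need >= 1 sequence per parental group", call. = FALSE)
    }
    pairs <- rbind(rep(ia, each = length(ib)), rep(ib, times = length(ia)))
  }
  npairs <- ncol(pairs)
  comparable <- is_unambiguous_base(m)
  dim(comparable) <- dim(m)
  # per-pair column indicators: D = differing comparable sites, C = comparable
  D <- matrix(0L, npairs, ncol(m))
  C <- matrix(0L, npairs, ncol(m))
  for (k in seq_len(npairs)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cmp <- comparable[i, ] & comparable[j, ]
    C[k, ] <- cmp
    D[k, ] <- cmp & (m[i, ] != m[j, ])
  }
  denom <- rowSums(C)
  if (any(denom == 0L)) {
    stop("undefined distance: zero comparable sites for a sample pair",
         call. = FALSE)
  }
  mean_p <- mean(rowSums(D) / denom)
  se_p <- NA_real_
  if (bootstrap_reps > 0L) {
    if (is.null(seed)) stop("bootstrap requires a seed", call. = FALSE)
    set.seed(as.integer(seed))
    L <- ncol(m)
    means <- vapply(seq_len(bootstrap_reps), function(r) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      num <- as.numeric(D %*% w)
      den <- as.numeric(C %*% w)
      ok <- den > 0
      mean(num[ok] / den[ok])
    }, numeric(1L))
    se_p <- stats::sd(means)
  }
  structure(
    list(mean_p = mean_p, se_p = se_p, mode = mode, n_pairs = npairs,
         bootstrap_reps = as.integer(bootstrap_reps),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "hyb_distance"
  )
}

#' @export
print.hyb_distance <- function(x, ...) {
  cat("<p-distance> mode=", x$mode, ": mean=",
      format_percent(x$mean_p), "%",
      if (!is.na(x$se_p)) paste0(", SE=", format_percent(x$se_p), "%"),
      " (", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

# Report rounding convention: percentages to one decimal place; internal
# values stay full precision.
format_percent <- function(p) formatC(round(100 * p, 1L), format = "f", digits = 1L)

#' Write a distance report as TSV
#'
#' @param results List of `hyb_distance` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_report <- function(results, path) {
  rows <- lapply(results, function(x) {
    data.frame(mode = x$mode,
               mean_p_percent = format_percent(x$mean_p),
               se_p_percent = if (is.na(x$se_p)) "NA" else format_percent(x$se_p),
               n_pairs = x$n_pairs,
               bootstrap_reps = x$bootstrap_reps,
               seed = x$seed,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
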