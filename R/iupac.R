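# IUPAC nucleotide ambiguity codes and small sequence helpers shared by all
# modules. Sequences are stored as plain uppercase character strings; column
# work goes through a character matrix built by aln_matrix().

#' IUPAC nucleotide code table
#'
#' Named character vector mapping each one-letter IUPAC nucleotide symbol to
#' the string of unambiguous bases it stands for (e.g. `R` -> `"AG"`).
#' The gap character `-` is part of the alignment alphabet but is not an
#' IUPAC base code and is not listed here.
#'
#' @format Named character vector of length 15.
#' @export
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG",
  N = "ACGT"
)

# Full alignment alphabet: IUPAC symbols plus the gap character.
ALN_ALPHABET <- c(names(IUPAC_CODES), "-")

#' Expand an IUPAC symbol to its base set
#'
#' @param symbol Single character, an IUPAC nucleotide code.
#' @return Character vector of unambiguous bases (sorted), e.g.
#'   `iupac_expand("R")` returns `c("A", "G")`.
#' @export
iupac_expand <- function(symbol) {
  stopifnot(length(symbol) == 1L)
  symbol <- toupper(symbol)
  if (!symbol %in% names(IUPAC_CODES)) {
    stop("not an IUPAC nucleotide symbol: '", symbol, "'", call. = FALSE)
  }
  sort(strsplit(IUPAC_CODES[[symbol]], "")[[1L]])
}

#' Collapse a set of bases to the IUPAC symbol covering it exactly
#'
#' @param bases Character vector of unambiguous bases (A/C/G/T), duplicates
#'   allowed.
#' @return Single IUPAC symbol whose expansion equals `unique(bases)`.
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  hit <- names(IUPAC_CODES)[match(key, vapply(IUPAC_CODES, function(s) {
    paste(sort(strsplit(s, "")[[1L]]), collapse = "")
  }, character(1L)))]
  if (is.na(hit)) stop("no IUPAC symbol for base set {", key, "}", call. = FALSE)
  hit
}

# TRUE for A/C/G/T, FALSE for ambiguity codes and gaps. Vectorised.
is_unambiguous_base <- function(x) x %in% c("A", "C", "G", "T")

# TRUE for 2-, 3- or 4-base ambiguity symbols (N included; callers decide
# whether N counts as a heterozygote call or a no-call).
is_ambiguity_code <- function(x) {
  x %in% names(IUPAC_CODES)[nchar(IUPAC_CODES) > 1L]
}
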