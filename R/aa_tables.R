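# Amino-acid alphabet, background composition, chemistry classes and
# monoisotopic mass constants used throughout the package.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes in alphabetical order. This ordering indexes the columns
#' of every position-specific scoring matrix and logo frequency matrix.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' A fixed average protein composition (Robinson-Robinson style), normalized
#' to sum to 1. Used as the null model for profile scores and as the sampling
#' distribution of the synthetic-sequence generator.
#'
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
aa_background <- function() {
  raw <- c(
    A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039,
    G = 0.074, H = 0.022, I = 0.051, K = 0.057, L = 0.090,
    M = 0.022, N = 0.045, P = 0.052, Q = 0.043, R = 0.051,
    S = 0.071, T = 0.058, V = 0.064, W = 0.013, Y = 0.032
  )
  raw / sum(raw)
}

# chemistry classes: nonpolar/polar/acidic/basic; His counted basic despite
# its catalytic role in the CitS dyad.
.chem_classes <- list(
  nonpolar = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
  polar    = c("S", "T", "N", "Q", "Y", "C"),
  acidic   = c("D", "E"),
  basic    = c("K", "R", "H")
)

#' Chemistry class of amino-acid residues
#'
#' Partitions the 20 residues into nonpolar \{A,V,L,I,M,F,W,P,G\},
#' polar \{S,T,N,Q,Y,C\}, acidic \{D,E\} and basic \{K,R,H\}. The gap
#' character `"-"` maps to class `"gap"`. This is the partition behind
#' chemistry-change novelty calls (e.g. acidic Glu at a pocket slot where
#' all characterized synthases carry nonpolar residues).
#'
#' @param aa Character vector of one-letter residue codes (and/or `"-"`).
#' @return Character vector of class labels, same length as `aa`.
#' @export
#' @examples
#' chemistry_class(c("M", "E", "-"))
chemistry_class <- function(aa) {
  stopifnot(is.character(aa))
  lut <- c(
    setNames(rep(names(.chem_classes), lengths(.chem_classes)),
             unlist(.chem_classes)),
    "-" = "gap"
  )
  bad <- setdiff(unique(aa), names(lut))
  if (length(bad) > 0L) {
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(lut[aa])
}

# residues as 0-based integer codes for the C++ scan kernel; -1 marks masked.
.aa_encode <- function(seq_chars) {
  m <- match(seq_chars, aa_alphabet()) - 1L
  m
}

# validate a protein string; returns the character vector of residues.
.check_protein <- function(protein, what = "protein") {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) == 0L) stop(what, " sequence is empty")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), aa_alphabet())
  if (length(bad) > 0L) {
    stop(what, " contains non-amino-acid symbol(s): ",
         paste(bad, collapse = ", "))
  }
  ch
}
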