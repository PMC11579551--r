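# Global alignment of candidate MT domains to the CitS reference and
# CitS-coordinate mapping through the alignment. This is the coordinate
# bridge behind statements like "Phe2044 of NvfA corresponds to Val2101 of
# CitS".

#' Globally align a candidate MT domain to the reference
#'
#' Needleman-Wunsch global alignment with the BLOSUM62 substitution matrix
#' and affine gap penalties (open 10, extend 1 by default), computed with
#' \pkg{Biostrings}. The result records both gapped rows and a per-column
#' map to ungapped reference / candidate positions.
#'
#' @param candidate_mt Candidate MT-domain amino-acid string.
#' @param ref A [reference_domain()] (or a plain amino-acid string).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Object of class `pairwise_alignment`: `aligned_ref`,
#'   `aligned_cand` (equal-length gapped strings), `score`, and integer
#'   vectors `ref_pos` / `cand_pos` giving, per alignment column, the
#'   1-based ungapped position or `NA` for a gap.
#' @export
align_to_reference <- function(candidate_mt, ref,
                               gap_open = 10, gap_extend = 1) {
  ref_seq <- if (inherits(ref, "reference_domain")) ref$sequence else ref
  .check_protein(candidate_mt, "candidate")
  .check_protein(ref_seq, "reference")
  mat <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(candidate_mt),
    subject = Biostrings::AAString(ref_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a_cand <- as.character(Biostrings::alignedPattern(aln))
  a_ref <- as.character(Biostrings::alignedSubject(aln))
  new_pairwise_alignment(a_ref, a_cand, Biostrings::score(aln),
                         ref_seq, candidate_mt)
}

# shared constructor: derives the column position maps and checks the
# degapping invariant
new_pairwise_alignment <- function(aligned_ref, aligned_cand, score,
                                   ref_seq, cand_seq) {
  stopifnot(nchar(aligned_ref) == nchar(aligned_cand))
  rch <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  cch <- strsplit(aligned_cand, "", fixed = TRUE)[[1]]
  if (paste(rch[rch != "-"], collapse = "") != ref_seq ||
      paste(cch[cch != "-"], collapse = "") != cand_seq) {
    stop("alignment rows do not degap to their input sequences")
  }
  ref_pos <- ifelse(rch == "-", NA_integer_, cumsum(rch != "-"))
  cand_pos <- ifelse(cch == "-", NA_integer_, cumsum(cch != "-"))
  structure(list(aligned_ref = aligned_ref, aligned_cand = aligned_cand,
                 score = score, ref_pos = as.integer(ref_pos),
                 cand_pos = as.integer(cand_pos)),
            class = "pairwise_alignment")
}

# BLOSUM62 from Biostrings' packaged data
get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Map a CitS-numbered position into candidate coordinates
#'
#' Finds the alignment column holding the reference residue at `cits_pos`
#' and returns the candidate position aligned to it, or `NA` if the
#' candidate has a gap there.
#'
#' @param aln A [align_to_reference()] result.
#' @param ref The [reference_domain()] used in the alignment.
#' @param cits_pos Residue position in CitS numbering.
#' @return Integer candidate position (1-based) or `NA` (site deleted in
#'   candidate).
#' @export
map_reference_position <- function(aln, ref, cits_pos) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(ref, "reference_domain"))
  idx <- as.integer(cits_pos) - ref$offset + 1L
  if (idx < 1L || idx > nchar(ref$sequence)) {
    stop("CitS position ", cits_pos, " is outside the reference range ",
         ref$offset, "-", ref$offset + nchar(ref$sequence) - 1L)
  }
  col <- which(aln$ref_pos == idx)
  stopifnot(length(col) == 1L)
  aln$cand_pos[col]
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f\n",
              nchar(x$aligned_ref), x$score))
  invisible(x)
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param aln A `pairwise_alignment`.
#' @param path Output path.
#' @param names Two record names (reference, candidate).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, names = c("reference", "candidate")) {
  write_fasta(setNames(c(aln$aligned_ref, aln$aligned_cand), names), path)
}
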