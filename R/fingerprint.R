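# Active-site fingerprints: the ordered readout of a candidate MT domain's
# residues at the 17 CitS substrate-binding-pocket positions, plus
# fingerprint distances and point-mutation proposals in candidate
# coordinates.

#' Extract the 17-residue active-site fingerprint of an MT domain
#'
#' Globally aligns the candidate to the reference and reads the candidate
#' residue aligned to each pocket position, in pocket order; a pocket
#' position deleted in the candidate reads as `"-"`.
#'
#' @param candidate_mt Candidate MT-domain amino-acid string (envelope plus
#'   the 30-residue C-terminal extension, see [extract_mt_domain()]).
#' @param ref A [reference_domain()]; default [cits_reference()].
#' @param source_name Label carried in the result.
#' @param aln Optional precomputed [align_to_reference()] result.
#' @return Object of class `mt_fingerprint`: `residues` (string, one
#'   character per pocket position), `source_name`, `cand_positions`
#'   (integer vector, `NA` at gaps), `cits_positions`.
#' @export
#' @examples
#' ref <- cits_reference()
#' fp <- extract_fingerprint(ref$sequence, ref)
#' fp$residues  # "LFVYINTNHEMWVFLWQ"
extract_fingerprint <- function(candidate_mt, ref = cits_reference(),
                                source_name = "candidate", aln = NULL) {
  stopifnot(inherits(ref, "reference_domain"))
  if (is.null(aln)) aln <- align_to_reference(candidate_mt, ref)
  cand_ch <- strsplit(candidate_mt, "", fixed = TRUE)[[1]]
  pos <- vapply(ref$pocket$cits_position, function(p) {
    map_reference_position(aln, ref, p)
  }, integer(1))
  res <- ifelse(is.na(pos), "-", cand_ch[ifelse(is.na(pos), 1L, pos)])
  structure(list(residues = paste(res, collapse = ""),
                 source_name = source_name,
                 cand_positions = pos,
                 cits_positions = ref$pocket$cits_position),
            class = "mt_fingerprint")
}

# accept an mt_fingerprint or a plain string; return the residue string
fingerprint_string <- function(fp) {
  if (inherits(fp, "mt_fingerprint")) fp$residues
  else if (is.character(fp) && length(fp) == 1L) fp
  else stop("expected an mt_fingerprint or a single string")
}

#' Hamming distance between fingerprints
#'
#' Counts positions whose characters differ. A gap against a residue counts
#' as one difference (a deleted pocket residue is functionally a change);
#' gap against gap counts zero.
#'
#' @param a,b `mt_fingerprint` objects or plain fingerprint strings of
#'   equal length.
#' @return Nonnegative integer.
#' @export
#' @examples
#' fingerprint_distance("LFVYINTNHEMWVFLWQ", "LFVYINTNHEEWVFLWQ")
fingerprint_distance <- function(a, b) {
  sa <- fingerprint_string(a)
  sb <- fingerprint_string(b)
  if (nchar(sa) != nchar(sb)) {
    stop("fingerprint length mismatch: ", nchar(sa), " vs ", nchar(sb))
  }
  sum(strsplit(sa, "", fixed = TRUE)[[1]] !=
        strsplit(sb, "", fixed = TRUE)[[1]])
}

#' Propose an active-site point mutation in candidate coordinates
#'
#' Maps a CitS pocket position into the candidate and renders a mutation
#' label `<orig><candidate_pos><target>` -- the style of the F2044L NvfA
#' variant (CitS 2101 site) and the E2052M/E2052L AsbPKS variants (CitS
#' 2094 site).
#'
#' @param candidate_mt Candidate MT-domain amino-acid string.
#' @param ref A [reference_domain()].
#' @param cits_pos Pocket site in CitS numbering.
#' @param target_aa Desired one-letter residue.
#' @param aln Optional precomputed alignment.
#' @return List with `label`, `position` (candidate coordinate),
#'   `original`, `target`, `cits_position`.
#' @export
propose_site_mutation <- function(candidate_mt, ref, cits_pos, target_aa,
                                  aln = NULL) {
  stopifnot(target_aa %in% aa_alphabet())
  if (is.null(aln)) aln <- align_to_reference(candidate_mt, ref)
  pos <- map_reference_position(aln, ref, cits_pos)
  if (is.na(pos)) {
    stop("site deleted in candidate: CitS ", cits_pos,
         " aligns to a gap")
  }
  orig <- substr(candidate_mt, pos, pos)
  if (orig == target_aa) {
    stop("candidate already carries ", target_aa, " at CitS ", cits_pos,
         " (candidate position ", pos, ")")
  }
  list(label = sprintf("%s%d%s", orig, pos, target_aa),
       position = pos, original = orig, target = target_aa,
       cits_position = as.integer(cits_pos))
}

#' Write fingerprints as TSV
#'
#' One row per fingerprint: name, residue string, and the comma-separated
#' candidate coordinates of each pocket slot (`-` for gaps).
#'
#' @param fps List of `mt_fingerprint` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  rows <- vapply(fps, function(fp) {
    coords <- ifelse(is.na(fp$cand_positions), "-",
                     as.character(fp$cand_positions))
    paste(fp$source_name, fp$residues, paste(coords, collapse = ","),
          sep = "\t")
  }, "")
  writeLines(c("name\tfingerprint\tcand_positions", rows), path)
  invisible(path)
}

#' @export
print.mt_fingerprint <- function(x, ...) {
  cat(sprintf("<mt_fingerprint> %s: %s\n", x$source_name, x$residues))
  invisible(x)
}
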