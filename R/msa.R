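# Reference-anchored multiple alignment: every member is pairwise-aligned
# to the reference and the pairwise alignments are merged on reference
# columns (a "star" MSA). Member insertions relative to the reference are
# left-justified in shared insertion blocks.

#' Build a reference-anchored star MSA
#'
#' @param domains Named character vector (>= 1) of amino-acid strings.
#' @param ref A [reference_domain()] (or plain string) used as the star
#'   center; default [cits_reference()].
#' @param include_reference Add the reference itself as the first row.
#' @param ... Passed to [align_to_reference()] (gap penalties).
#' @return Object of class `star_msa`: `names`, `rows` (equal-length gapped
#'   strings), `ref_columns` (alignment column of each ungapped reference
#'   position).
#' @export
star_msa <- function(domains, ref = cits_reference(),
                     include_reference = FALSE, ...) {
  if (length(domains) < 1L) stop("star_msa needs at least one sequence")
  if (is.null(names(domains)) || any(!nzchar(names(domains)))) {
    names(domains) <- paste0("seq", seq_along(domains))
  }
  ref_seq <- if (inherits(ref, "reference_domain")) ref$sequence else ref
  R <- nchar(ref_seq)
  ref_ch <- strsplit(ref_seq, "", fixed = TRUE)[[1]]

  # per member: matched residue ('-' if deleted) at each reference position,
  # and the insertion string after reference position i (i = 0 for leading)
  matched <- matrix("-", nrow = length(domains), ncol = R)
  inserts <- vector("list", length(domains))
  for (m in seq_along(domains)) {
    aln <- align_to_reference(domains[[m]], ref_seq, ...)
    rch <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
    cch <- strsplit(aln$aligned_cand, "", fixed = TRUE)[[1]]
    ins <- rep("", R + 1L)
    last_ref <- 0L
    for (k in seq_along(rch)) {
      if (rch[k] == "-") {
        ins[last_ref + 1L] <- paste0(ins[last_ref + 1L], cch[k])
      } else {
        last_ref <- aln$ref_pos[k]
        matched[m, last_ref] <- cch[k]
      }
    }
    inserts[[m]] <- ins
  }

  ins_len <- apply(do.call(rbind, lapply(inserts, nchar)), 2L, max)
  pad <- function(s, w) {
    paste0(s, strrep("-", w - nchar(s)))  # left-justified insertions
  }
  rows <- vapply(seq_along(domains), function(m) {
    pieces <- character(2L * R + 1L)
    pieces[1L] <- pad(inserts[[m]][1L], ins_len[1L])
    for (i in seq_len(R)) {
      pieces[2L * i] <- matched[m, i]
      pieces[2L * i + 1L] <- pad(inserts[[m]][i + 1L], ins_len[i + 1L])
    }
    paste(pieces, collapse = "")
  }, "")
  names(rows) <- names(domains)

  # alignment column index of each reference position
  ref_columns <- cumsum(c(ins_len[1L] + 1L,
                          if (R > 1L) ins_len[2:R] + 1L))
  if (include_reference) {
    ref_row <- paste(vapply(seq_len(R), function(i) {
      paste0(ref_ch[i], strrep("-", ins_len[i + 1L]))
    }, ""), collapse = "")
    ref_row <- paste0(strrep("-", ins_len[1L]), ref_row)
    rows <- c(setNames(ref_row, "reference"), rows)
  }

  out <- structure(list(names = names(rows), rows = rows,
                        ref_columns = as.integer(ref_columns)),
                   class = "star_msa")
  # invariant: degapping any row reproduces its input
  for (m in seq_along(domains)) {
    got <- gsub("-", "", rows[[if (include_reference) m + 1L else m]],
                fixed = TRUE)
    stopifnot(identical(got, unname(domains[[m]])))
  }
  out
}

#' @export
print.star_msa <- function(x, ...) {
  cat(sprintf("<star_msa> %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[[1L]])))
  invisible(x)
}

#' Write a star MSA as aligned FASTA
#'
#' @param msa A `star_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  write_fasta(msa$rows, path)
}
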