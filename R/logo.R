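# Sequence-logo matrices: per-column residue frequencies and information
# content in bits, IC_i = log2(20) - H_i - e_n, with the small-sample
# correction e_n = 19 / (2 ln(2) n) computed from the number of non-gap
# residues observed in the column.

#' Build a sequence-logo matrix
#'
#' @param strings Character vector (>= 1) of equal-length residue strings
#'   (fingerprints or MSA columns); gaps `"-"` are excluded from column
#'   counts.
#' @param correct_small_sample Apply the small-sample correction
#'   `e_n = 19 / (2 ln(2) n)` (default `TRUE`).
#' @return Object of class `seq_logo`: `freq` (positions x 20 matrix of
#'   frequencies summing to 1 over non-gap residues), `ic` (information
#'   content in bits, clamped to `[0, log2 20]`), `n` (non-gap count per
#'   column).
#' @export
#' @examples
#' logo <- build_logo(c("MM", "ME"), correct_small_sample = FALSE)
#' logo$ic
build_logo <- function(strings, correct_small_sample = TRUE) {
  stopifnot(is.character(strings))
  if (length(strings) < 1L) stop("build_logo needs at least one string")
  w <- unique(nchar(strings))
  if (length(w) != 1L) stop("logo input strings differ in length")
  mat <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), c(aa_alphabet(), "-"))
  if (length(bad) > 0L) stop("bad symbol(s) in logo input: ",
                             paste(bad, collapse = ","))
  P <- w
  freq <- matrix(0, nrow = P, ncol = 20L,
                 dimnames = list(NULL, aa_alphabet()))
  ic <- numeric(P)
  nn <- integer(P)
  max_ic <- log2(20)
  for (i in seq_len(P)) {
    col <- mat[, i]
    col <- col[col != "-"]
    nn[i] <- length(col)
    if (nn[i] == 0L) next
    f <- tabulate(match(col, aa_alphabet()), nbins = 20L) / nn[i]
    freq[i, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    en <- if (correct_small_sample) 19 / (2 * log(2) * nn[i]) else 0
    ic[i] <- min(max(max_ic - h - en, 0), max_ic)
  }
  structure(list(freq = freq, ic = ic, n = nn), class = "seq_logo")
}

#' Write a logo matrix as TSV
#'
#' One row per position: `position`, the 20 residue frequencies, `ic`
#' (bits) and `n` (non-gap sample size).
#'
#' @param logo A [build_logo()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo <- function(logo, path) {
  df <- data.frame(position = seq_along(logo$ic), logo$freq,
                   ic = logo$ic, n = logo$n, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.seq_logo <- function(x, ...) {
  cat(sprintf("<seq_logo> %d positions, mean IC %.2f bits\n",
              length(x$ic), mean(x$ic)))
  invisible(x)
}
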