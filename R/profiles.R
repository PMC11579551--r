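# Position-specific scoring profiles built from seed alignments.
# Columns with more than 50% gaps are treated as insert states and dropped;
# remaining match columns score residue a at column c as
#   log2((f_ca + alpha * q_a) / ((1 + alpha) * q_a))
# in bits, where f_ca is the observed column frequency, q the background
# composition and alpha the pseudocount weight.

DOMAIN_FAMILIES <- c("SAT", "KS", "AT", "PT", "ACP", "MT")

#' Construct a seed alignment
#'
#' @param family Domain family, one of `"SAT"`, `"KS"`, `"AT"`, `"PT"`,
#'   `"ACP"`, `"MT"`.
#' @param rows Character vector (>= 2) of equal-length gapped amino-acid
#'   strings; gap character `"-"`.
#' @return Object of class `seed_alignment`.
#' @export
seed_alignment <- function(family, rows) {
  family <- match.arg(family, DOMAIN_FAMILIES)
  stopifnot(is.character(rows))
  if (length(rows) < 2L) stop("seed alignment needs >= 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("seed alignment rows differ in length")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), c(aa_alphabet(), "-"))
  if (length(bad) > 0L) stop("bad symbol(s) in seed alignment: ",
                             paste(bad, collapse = ","))
  if (!any(colSums(mat != "-") == nrow(mat))) {
    stop("seed alignment has no fully ungapped column")
  }
  structure(list(family = family, rows = rows),
            class = "seed_alignment")
}

#' Read a seed alignment from aligned FASTA
#'
#' @param path Aligned FASTA file.
#' @param family Domain family label; if `NULL`, taken from the file name
#'   prefix (e.g. `MT_...afa`).
#' @return A [seed_alignment()].
#' @export
read_seed_alignment <- function(path, family = NULL) {
  if (is.null(family)) {
    family <- sub("_.*$", "", basename(path))
  }
  set <- Biostrings::readAAStringSet(path)
  seed_alignment(family, as.character(set))
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' @param seed A [seed_alignment()].
#' @param pseudocount_weight Nonnegative pseudocount weight `alpha`; `0`
#'   scores observed frequencies directly, large values shrink all scores
#'   toward 0.
#' @param background Background residue frequencies; default
#'   [aa_background()].
#' @return Object of class `domain_profile` with the family, number of
#'   match columns (`length`), the `length x 20` score matrix in bits
#'   (columns ordered as [aa_alphabet()]), the background, and the indices
#'   of the retained seed columns.
#' @export
#' @examples
#' seed <- seed_alignment("MT", c("ACDACD", "ACDACD"))
#' prof <- build_profile(seed, pseudocount_weight = 0)
#' prof$length
build_profile <- function(seed, pseudocount_weight = 0.5,
                          background = aa_background()) {
  stopifnot(inherits(seed, "seed_alignment"))
  alpha <- pseudocount_weight
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  q <- background[aa_alphabet()]
  stopifnot(!anyNA(q), all(q > 0))
  q <- q / sum(q)
  mat <- do.call(rbind, strsplit(seed$rows, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac <= 0.5)
  if (length(match_cols) == 0L) stop("no match columns after insert filtering")
  L <- length(match_cols)
  scores <- matrix(0, nrow = L, ncol = 20L,
                   dimnames = list(NULL, aa_alphabet()))
  for (k in seq_len(L)) {
    col <- mat[, match_cols[k]]
    col <- col[col != "-"]
    f <- tabulate(match(col, aa_alphabet()), nbins = 20L) / length(col)
    scores[k, ] <- log2((f + alpha * q) / ((1 + alpha) * q))
  }
  if (any(!is.finite(scores))) {
    # alpha = 0 with unobserved residues: floor at a strong penalty so the
    # dynamic programming stays finite
    scores[!is.finite(scores)] <- -20
  }
  structure(list(family = seed$family, length = L, scores = scores,
                 background = q, match_cols = match_cols),
            class = "domain_profile")
}

#' Consensus sequence of a profile
#'
#' Highest-scoring residue at each match column; used by the synthetic PKS
#' generator as the planted domain block.
#'
#' @param profile A [build_profile()] result.
#' @return Amino-acid string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  stopifnot(inherits(profile, "domain_profile"))
  paste(aa_alphabet()[apply(profile$scores, 1L, which.max)], collapse = "")
}

#' Packaged seed alignments and profiles
#'
#' The package ships one synthetic seed alignment per domain family under
#' `extdata/seeds/` (`<FAMILY>_synthetic_seed.afa`). These are fixtures:
#' deterministic ancestor sequences diversified by point substitutions, with
#' the MT ancestor equal to the packaged CitS reference sequence so that the
#' whole scan-extract-fingerprint chain is exercised end to end. Substitute
#' curated seeds for production mining.
#'
#' @param families Families to load; default all six.
#' @param pseudocount_weight Passed to [build_profile()].
#' @return `packaged_seeds()`: named list of [seed_alignment()]s.
#' @export
packaged_seeds <- function(families = DOMAIN_FAMILIES) {
  out <- lapply(families, function(f) {
    path <- system.file("extdata", "seeds",
                        paste0(f, "_synthetic_seed.afa"),
                        package = "pksmine", mustWork = TRUE)
    read_seed_alignment(path, family = f)
  })
  names(out) <- families
  out
}

#' @rdname packaged_seeds
#' @return `packaged_profiles()`: named list of `domain_profile`s.
#' @export
packaged_profiles <- function(families = DOMAIN_FAMILIES,
                              pseudocount_weight = 0.5) {
  lapply(packaged_seeds(families), build_profile,
         pseudocount_weight = pseudocount_weight)
}
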