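# Profile scanning of candidate proteins: hit envelopes, the MT-domain
# 30-residue C-terminal extension rule, and NR-PKS architecture
# classification.

#' Scan a protein with a domain profile
#'
#' Local alignment of the profile's match columns against the protein
#' (affine gaps, dynamic programming). Hits with score at or above
#' `threshold_bits` are reported best-first; after each accepted hit its
#' envelope is masked, so reported envelopes never overlap. MT hits carry
#' `extended_end = min(end + 30, protein length)` -- the C-terminal
#' extension applied before MT domains are analyzed -- while all other
#' families have `extended_end = end`.
#'
#' @param protein Amino-acid string.
#' @param profile A [build_profile()] result.
#' @param threshold_bits Minimum reported score (default 40 bits).
#' @param gap_open,gap_extend Affine gap penalties in bits (defaults 8, 1).
#' @param max_hits Safety cap on reported hits per profile.
#' @return `data.frame` with columns `family`, `start`, `end`, `score`,
#'   `extended_end` (1-based inclusive coordinates), ordered by decreasing
#'   score. Zero rows when nothing reaches the threshold.
#' @export
scan_protein <- function(protein, profile, threshold_bits = 40,
                         gap_open = 8, gap_extend = 1, max_hits = 25L) {
  stopifnot(inherits(profile, "domain_profile"))
  ch <- .check_protein(protein)
  codes <- .aa_encode(ch)
  n <- length(codes)
  hits <- list()
  repeat {
    res <- .pssm_local_scan(profile$scores, codes, gap_open, gap_extend)
    if (res$score < threshold_bits || res$seq_start < 1L ||
        length(hits) >= max_hits) {
      break
    }
    start <- res$seq_start
    end <- res$seq_end
    ext <- if (profile$family == "MT") min(end + 30L, n) else end
    hits[[length(hits) + 1L]] <- data.frame(
      family = profile$family, start = start, end = end,
      score = res$score, extended_end = as.integer(ext),
      stringsAsFactors = FALSE)
    codes[start:end] <- -1L
  }
  if (length(hits) == 0L) {
    return(data.frame(family = character(), start = integer(),
                      end = integer(), score = numeric(),
                      extended_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Scan a protein with several profiles
#'
#' Convenience wrapper over [scan_protein()]: scans each family's profile
#' and returns all hits sorted by start coordinate.
#'
#' @param protein Amino-acid string.
#' @param profiles Named list of `domain_profile`s, e.g.
#'   [packaged_profiles()].
#' @param ... Passed to [scan_protein()].
#' @return Combined hit `data.frame`, ordered by `start`.
#' @export
scan_domains <- function(protein, profiles = packaged_profiles(), ...) {
  all_hits <- do.call(rbind, lapply(profiles, scan_protein,
                                    protein = protein, ...))
  if (is.null(all_hits) || nrow(all_hits) == 0L) {
    return(scan_protein(protein, profiles[[1L]], threshold_bits = Inf))
  }
  rownames(all_hits) <- NULL
  all_hits[order(all_hits$start), , drop = FALSE]
}

#' Extract an MT domain with the C-terminal extension rule
#'
#' Returns the protein substring from the hit envelope start through
#' `min(end + 30, length)`: the detected MT envelope plus 30 additional
#' C-terminal residues (clipped at the protein end).
#'
#' @param protein Amino-acid string the hit was found on.
#' @param hit One row of a [scan_protein()] result with `family == "MT"`.
#' @return The extracted MT-domain amino-acid string.
#' @export
extract_mt_domain <- function(protein, hit) {
  stopifnot(is.data.frame(hit), nrow(hit) == 1L)
  if (hit$family != "MT") {
    stop("extract_mt_domain requires an MT hit, got family '",
         hit$family, "'")
  }
  n <- nchar(protein)
  if (hit$start < 1L || hit$end > n || hit$start > hit$end) {
    stop("hit envelope [", hit$start, ", ", hit$end,
         "] is invalid for a protein of length ", n)
  }
  substr(protein, hit$start, min(hit$end + 30L, n))
}

#' Classify domain architecture
#'
#' Orders hits by start coordinate and joins the family labels with `-`.
#' The NR-PKS flag is `TRUE` when the core KS, AT, PT and ACP domains are
#' all present (SAT is optional); reducing domains are outside this
#' locator's six-family model.
#'
#' @param hits Hit `data.frame` for one protein ([scan_domains()]).
#' @return List with `architecture` (string, `""` for no hits) and
#'   `nr_pks` (logical).
#' @export
#' @examples
#' h <- data.frame(family = c("KS", "SAT"), start = c(200L, 10L),
#'                 end = c(380L, 150L), score = c(50, 40),
#'                 extended_end = c(380L, 150L))
#' classify_architecture(h)$architecture
classify_architecture <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    return(list(architecture = "", nr_pks = FALSE))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  if (nrow(hits) > 1L) {
    overlap <- hits$start[-1L] <= hits$end[-nrow(hits)]
    diff_fam <- hits$family[-1L] != hits$family[-nrow(hits)]
    if (any(overlap & diff_fam)) {
      k <- which(overlap & diff_fam)[1L]
      stop("ambiguous architecture: overlapping hits of different families (",
           hits$family[k], " and ", hits$family[k + 1L], ")")
    }
  }
  arch <- paste(hits$family, collapse = "-")
  core <- c("KS", "AT", "PT", "ACP")
  list(architecture = arch, nr_pks = all(core %in% hits$family))
}

#' Write domain hits as TSV
#'
#' @param hits Hit `data.frame` with an additional `name` column (or a
#'   single protein's hits plus `name`).
#' @param path Output path.
#' @param name Protein name used when `hits` has no `name` column.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, name = "protein") {
  if (!"name" %in% names(hits)) hits$name <- name
  out <- hits[, c("name", "family", "start", "end", "score", "extended_end")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
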