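# Novelty mining: per-slot comparison of a candidate fingerprint against
# the catalog of characterized synthases. A slot is "novel" when the
# candidate's residue has never been observed there; it additionally
# changes chemistry when its class (nonpolar/polar/acidic/basic) is absent
# from the slot's class set -- the signal (acidic Glu at the CitS-2094 slot,
# nonpolar in every characterized synthase) that singled out AsbPKS.

# per-slot residue matrix of a catalog: rows = entries, cols = slots
catalog_slot_matrix <- function(catalog) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  do.call(rbind, strsplit(catalog$fingerprint, "", fixed = TRUE))
}

#' Per-position novelty of a fingerprint against a catalog
#'
#' @param fp An `mt_fingerprint` or fingerprint string.
#' @param catalog A `pks_catalog` ([load_catalog()]).
#' @param ref Reference domain supplying the CitS numbering of the slots;
#'   default [cits_reference()].
#' @return List with `novel_positions` and `class_change_positions`
#'   (integer vectors of CitS positions; the second is a subset of the
#'   first).
#' @export
position_novelty <- function(fp, catalog, ref = cits_reference()) {
  s <- fingerprint_string(fp)
  slots <- catalog_slot_matrix(catalog)
  if (nchar(s) != ncol(slots)) {
    stop("fingerprint length ", nchar(s), " != catalog slot count ",
         ncol(slots))
  }
  cand <- strsplit(s, "", fixed = TRUE)[[1]]
  cits <- ref$pocket$cits_position
  stopifnot(length(cits) == length(cand))
  novel <- logical(length(cand))
  class_change <- logical(length(cand))
  for (k in seq_along(cand)) {
    seen <- slots[, k]
    novel[k] <- !(cand[k] %in% seen)
    if (novel[k]) {
      class_change[k] <- !(chemistry_class(cand[k]) %in%
                             chemistry_class(unique(seen)))
    }
  }
  list(novel_positions = cits[novel],
       class_change_positions = cits[class_change])
}

#' Novelty score of a fingerprint
#'
#' `score = |novel_positions| + w_class * |class_change_positions|`; with
#' the default `w_class = 2` a single chemistry-changing residue outranks
#' two merely unseen same-class residues.
#'
#' @inheritParams position_novelty
#' @param w_class Nonnegative weight on chemistry-class changes.
#' @return Nonnegative numeric score.
#' @export
novelty_score <- function(fp, catalog, w_class = 2, ref = cits_reference()) {
  stopifnot(is.numeric(w_class), w_class >= 0)
  pn <- position_novelty(fp, catalog, ref)
  length(pn$novel_positions) + w_class * length(pn$class_change_positions)
}

#' Predict a methylation pattern by nearest catalog neighbor
#'
#' Transfers the methylation pattern of the minimum-Hamming-distance
#' catalog entry. When several entries tie at the minimum and disagree on
#' the pattern, the prediction is ambiguous and the tied set is reported.
#'
#' @inheritParams position_novelty
#' @return List with `pattern` (a [methylation_pattern()] or `NULL`),
#'   `ambiguous` (logical), `min_distance`, `nearest` (character vector of
#'   entry names at the minimum distance).
#' @export
predict_pattern <- function(fp, catalog, ref = cits_reference()) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  s <- fingerprint_string(fp)
  d <- vapply(catalog$fingerprint, fingerprint_distance, integer(1), a = s,
              USE.NAMES = FALSE)
  mind <- min(d)
  hits <- which(d == mind)
  pats <- lapply(hits, function(i) catalog_pattern(catalog, i))
  agree <- all(vapply(pats, pattern_equal, logical(1), b = pats[[1L]]))
  list(pattern = if (agree) pats[[1L]] else NULL,
       ambiguous = !agree,
       min_distance = as.integer(mind),
       nearest = catalog$name[hits])
}

#' Full novelty report for one candidate
#'
#' @inheritParams novelty_score
#' @param name Candidate name recorded in the report.
#' @return Object of class `novelty_report` with fields `name`,
#'   `fingerprint`, `novel_positions`, `class_change_positions`,
#'   `min_distance`, `nearest`, `predicted_pattern` (string form,
#'   `"ambiguous"` when tied entries disagree), `pattern` (object or
#'   `NULL`), `score`.
#' @export
novelty_report <- function(fp, catalog, name = NULL, w_class = 2,
                           ref = cits_reference()) {
  if (is.null(name)) {
    name <- if (inherits(fp, "mt_fingerprint")) fp$source_name else "candidate"
  }
  pn <- position_novelty(fp, catalog, ref)
  pred <- predict_pattern(fp, catalog, ref)
  score <- length(pn$novel_positions) +
    w_class * length(pn$class_change_positions)
  structure(list(
    name = name,
    fingerprint = fingerprint_string(fp),
    novel_positions = pn$novel_positions,
    class_change_positions = pn$class_change_positions,
    min_distance = pred$min_distance,
    nearest = pred$nearest,
    predicted_pattern = if (pred$ambiguous) "ambiguous"
                        else format(pred$pattern),
    pattern = pred$pattern,
    score = score
  ), class = "novelty_report")
}

#' Rank candidate novelty reports
#'
#' Descending score; ties broken by `min_distance` descending, then by
#' name ascending. Stable under permutation of the input.
#'
#' @param reports List of [novelty_report()] objects.
#' @return The same reports, reordered.
#' @export
rank_candidates <- function(reports) {
  if (length(reports) == 0L) return(reports)
  score <- vapply(reports, `[[`, numeric(1), "score")
  mind <- vapply(reports, `[[`, integer(1), "min_distance")
  nm <- vapply(reports, `[[`, "", "name")
  reports[order(-score, -mind, nm, method = "radix")]
}

#' @export
print.novelty_report <- function(x, ...) {
  cat(sprintf("<novelty_report> %s  score %.1f  min_distance %d\n",
              x$name, x$score, x$min_distance))
  cat(sprintf("  fingerprint: %s\n", x$fingerprint))
  if (length(x$novel_positions) > 0L) {
    cat("  novel at CitS:", paste(x$novel_positions, collapse = ","), "\n")
  }
  if (length(x$class_change_positions) > 0L) {
    cat("  chemistry change at CitS:",
        paste(x$class_change_positions, collapse = ","), "\n")
  }
  cat(sprintf("  nearest: %s (predicted %s)\n",
              paste(x$nearest, collapse = ","), x$predicted_pattern))
  invisible(x)
}
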