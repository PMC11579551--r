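# Molecular formulas, monoisotopic masses and electrospray adduct m/z.
# Protonation uses the proton mass (1.00727646 Da), not the hydrogen-atom
# mass: that is the electrospray adduct convention and what reproduces an
# [M+H]+ calcd of 221.0808 for C12H12O4 (anhydrosclerotinin B).

# monoisotopic atomic masses, pinned to 8 decimals
.monoisotopic_masses <- c(
  C = 12.00000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376200,
  Na = 22.98976928
)

PROTON_MASS <- 1.00727646

.adduct_shifts <- c(
  "[M+H]+" = PROTON_MASS,
  "[M-H]-" = -PROTON_MASS,
  "[M+Na]+" = 22.98922
)

#' Parse a molecular formula
#'
#' Hill-notation style without parentheses, e.g. `"C12H12O4"`; element
#' counts default to 1 when omitted.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts (class
#'   `molecular_formula`).
#' @export
#' @examples
#' parse_formula("C12H12O4")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: ", text)
  }
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% names(.monoisotopic_masses)) {
      stop("unknown element symbol: ", el)
    }
    num <- sub("^[A-Za-z]+", "", tok)
    k <- if (nzchar(num)) as.integer(num) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  structure(counts, class = "molecular_formula")
}

#' Format a molecular formula
#'
#' @param x A [parse_formula()] result.
#' @param ... Unused.
#' @return Hill-style formula string (C, H first, then alphabetical).
#' @export
format.molecular_formula <- function(x, ...) {
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste(vapply(ord, function(e) {
    if (x[[e]] == 0L) "" else if (x[[e]] == 1L) e else paste0(e, x[[e]])
  }, ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of pinned monoisotopic atomic masses (C exactly 12, H 1.00782503,
#' N 14.00307401, O 15.99491462, S 31.97207117, P 30.97376200,
#' Na 22.98976928).
#'
#' @param f A [parse_formula()] result or formula string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C12H12O4")  # 220.0736
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molecular_formula"))
  if (sum(f) == 0L) stop("formula has no atoms")
  sum(.monoisotopic_masses[names(f)] * as.integer(f))
}

#' Adduct m/z of a molecular formula
#'
#' Supported adducts: `[M+H]+` (+1.00727646), `[M-H]-` (-1.00727646),
#' `[M+Na]+` (+22.98922). All adducts are singly charged.
#'
#' @param f A [parse_formula()] result or formula string.
#' @param adduct Adduct label.
#' @return m/z in Th.
#' @export
#' @examples
#' adduct_mz("C12H12O4", "[M+H]+")  # 221.0808
adduct_mz <- function(f, adduct = "[M+H]+") {
  if (!adduct %in% names(.adduct_shifts)) {
    stop("unknown adduct '", adduct, "'; supported: ",
         paste(names(.adduct_shifts), collapse = ", "))
  }
  monoisotopic_mass(f) + .adduct_shifts[[adduct]]
}
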