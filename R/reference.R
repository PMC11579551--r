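# The CitS MT-domain reference: sequence in CitS numbering plus the 17
# annotated substrate-binding-pocket positions (two of which form the
# His2067/Glu2093 catalytic dyad). All candidate fingerprints are read out
# against this coordinate system.

#' Construct a reference MT domain
#'
#' A reference domain couples an amino-acid sequence with an absolute
#' residue-numbering offset (CitS numbering) and an ordered table of
#' annotated substrate-binding-pocket positions.
#'
#' @param name Identifier, e.g. `"CitS_MT"`.
#' @param sequence Amino-acid string of the reference MT-domain region.
#' @param offset CitS residue number of the first sequence character.
#' @param pocket `data.frame` with columns `cits_position` (integer, strictly
#'   increasing), `reference_residue` (one-letter code) and `role`
#'   (`"pocket"` or `"catalytic_dyad"`).
#' @return An object of class `reference_domain`.
#' @seealso [cits_reference()], [validate_reference()]
#' @export
reference_domain <- function(name, sequence, offset, pocket) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.numeric(offset), length(offset) == 1L,
            is.data.frame(pocket))
  need <- c("cits_position", "reference_residue", "role")
  if (!all(need %in% names(pocket))) {
    stop("pocket table must have columns: ", paste(need, collapse = ", "))
  }
  pocket <- pocket[, need]
  pocket$cits_position <- as.integer(pocket$cits_position)
  ref <- structure(
    list(name = name, sequence = sequence, offset = as.integer(offset),
         pocket = pocket),
    class = "reference_domain"
  )
  ref
}

#' Validate a reference domain annotation
#'
#' Runs every consistency check as a report entry rather than an error:
#' pocket positions inside the sequence range, strictly increasing order,
#' declared residues matching the sequence, exactly 17 pocket positions,
#' and the catalytic dyad (His at CitS 2067, Glu at CitS 2093).
#'
#' @param ref A [reference_domain()].
#' @return `data.frame` with columns `check`, `pass`, `detail`; attribute
#'   `all_pass` is `TRUE` when every check passed.
#' @export
#' @examples
#' rep <- validate_reference(cits_reference())
#' attr(rep, "all_pass")
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "reference_domain"))
  n <- nchar(ref$sequence)
  pk <- ref$pocket
  lo <- ref$offset
  hi <- ref$offset + n - 1L
  checks <- list()
  add <- function(check, pass, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  in_range <- pk$cits_position >= lo & pk$cits_position <= hi
  add("positions_in_range", all(in_range),
      if (all(in_range)) sprintf("all within [%d, %d]", lo, hi)
      else paste("outside range:",
                 paste(pk$cits_position[!in_range], collapse = ",")))

  inc <- !is.unsorted(pk$cits_position, strictly = TRUE)
  add("positions_strictly_increasing", inc,
      if (inc) "ok" else "pocket positions not strictly increasing")

  seq_ch <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  idx <- pk$cits_position - lo + 1L
  idx_ok <- idx >= 1L & idx <= n
  match_res <- idx_ok & seq_ch[pmax(pmin(idx, n), 1L)] == pk$reference_residue
  add("residues_match_sequence", all(match_res),
      if (all(match_res)) "declared residues agree with sequence"
      else paste("mismatch at CitS",
                 paste(pk$cits_position[!match_res], collapse = ",")))

  add("pocket_count_17", nrow(pk) == 17L,
      sprintf("%d pocket positions", nrow(pk)))

  dyad <- pk[pk$role == "catalytic_dyad", ]
  dyad_ok <- nrow(dyad) == 2L &&
    any(dyad$cits_position == 2067L & dyad$reference_residue == "H") &&
    any(dyad$cits_position == 2093L & dyad$reference_residue == "E")
  add("catalytic_dyad_H2067_E2093", dyad_ok,
      if (dyad_ok) "His2067 / Glu2093"
      else paste0("dyad rows: ",
                  paste(sprintf("%s%d", dyad$reference_residue,
                                dyad$cits_position), collapse = ", ")))

  aa_ok <- all(pk$reference_residue %in% aa_alphabet())
  add("residues_in_alphabet", aa_ok,
      if (aa_ok) "ok" else "non-standard residue in pocket table")

  out <- do.call(rbind, checks)
  attr(out, "all_pass") <- all(out$pass)
  out
}

# stop with a readable message if the reference fails validation;
# structural checks always fail hard, the pocket-count and dyad checks are
# annotation conventions enforced only when strict = TRUE (toy references
# with fewer pocket positions are legitimate test objects)
assert_valid_reference <- function(ref, strict = FALSE) {
  rep <- validate_reference(ref)
  if (!strict) {
    rep <- rep[!rep$check %in% c("pocket_count_17",
                                 "catalytic_dyad_H2067_E2093"), ]
  }
  if (!all(rep$pass)) {
    bad <- rep[!rep$pass, ]
    stop("invalid reference domain: ",
         paste(sprintf("%s (%s)", bad$check, bad$detail), collapse = "; "))
  }
  invisible(ref)
}

#' Self-fingerprint of a reference domain
#'
#' Reads the declared reference residues in pocket order. For the packaged
#' CitS annotation this is `"LFVYINTNHEMWVFLWQ"`.
#'
#' @param ref A validated [reference_domain()].
#' @return Single string, one character per pocket position.
#' @export
#' @examples
#' reference_self_fingerprint(cits_reference())
reference_self_fingerprint <- function(ref) {
  assert_valid_reference(ref)
  paste(ref$pocket$reference_residue, collapse = "")
}

#' Read a reference domain from its text format
#'
#' The format is line-oriented: `#` comments; `name:` and `offset:` headers;
#' a `sequence:` header followed by one or more sequence lines; a `pocket:`
#' header followed by whitespace-separated `cits_position residue role`
#' rows.
#'
#' @param path File path.
#' @return A [reference_domain()].
#' @export
read_reference <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  kv <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) != 1L) stop("reference file needs exactly one '",
                                key, ":' line")
    trimws(sub(paste0("^", key, ":"), "", hit))
  }
  name <- kv("name")
  offset <- as.integer(kv("offset"))
  i_seq <- grep("^sequence:", lines)
  i_pk <- grep("^pocket:", lines)
  if (length(i_seq) != 1L || length(i_pk) != 1L || i_pk <= i_seq) {
    stop("reference file must contain 'sequence:' followed by 'pocket:'")
  }
  sequence <- paste(trimws(lines[(i_seq + 1L):(i_pk - 1L)]), collapse = "")
  rows <- lines[(i_pk + 1L):length(lines)]
  parts <- strsplit(trimws(rows), "\\s+")
  if (any(lengths(parts) != 3L)) stop("malformed pocket row in ", path)
  pk <- data.frame(
    cits_position = as.integer(vapply(parts, `[`, "", 1L)),
    reference_residue = vapply(parts, `[`, "", 2L),
    role = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  reference_domain(name, sequence, offset, pk)
}

#' Write a reference domain to its text format
#'
#' @param ref A [reference_domain()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_domain"))
  seq_wrapped <- gsub("(.{60})", "\\1\n", ref$sequence)
  seq_wrapped <- strsplit(seq_wrapped, "\n", fixed = TRUE)[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("name: %s", ref$name),
    sprintf("offset: %d", ref$offset),
    "sequence:",
    seq_wrapped,
    "pocket:",
    sprintf("%d\t%s\t%s", ref$pocket$cits_position,
            ref$pocket$reference_residue, ref$pocket$role)
  ), con)
  invisible(path)
}

#' The packaged CitS MT-domain reference
#'
#' The annotation carries the 17 substrate-binding-pocket residues of the
#' citrinin synthase (CitS/PksCT) MT domain in CitS numbering -- Leu1938,
#' Phe1942, Val1954, Tyr1955, Ile1960, Asn1961, Thr2063, Asn2064, His2067,
#' Glu2093, Met2094, Trp2100, Val2101, Phe2105, Leu2108, Trp2111, Gln2153 --
#' with His2067/Glu2093 marked as the catalytic dyad. The carrier sequence
#' is a synthetic stand-in spanning CitS 1901-2200 that places those
#' residues at their annotated coordinates; users with the real CitS protein
#' can substitute it via [reference_domain()] or [read_reference()] --
#' correctness of the fingerprint readout is defined by the annotation, not
#' by a particular database record.
#'
#' @return A validated [reference_domain()].
#' @export
#' @examples
#' ref <- cits_reference()
#' nrow(ref$pocket)
cits_reference <- function() {
  path <- system.file("extdata", "cits_mt_synthetic_reference.txt",
                      package = "pksmine", mustWork = TRUE)
  ref <- read_reference(path)
  assert_valid_reference(ref, strict = TRUE)
  ref
}

#' @export
print.reference_domain <- function(x, ...) {
  cat(sprintf("<reference_domain> %s: %d aa, numbering %d-%d, %d pocket positions\n",
              x$name, nchar(x$sequence), x$offset,
              x$offset + nchar(x$sequence) - 1L, nrow(x$pocket)))
  invisible(x)
}
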