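# Methylation patterns and the catalog of characterized synthases.
# A catalog pairs each synthase's 17-residue active-site fingerprint with
# its methylation pattern (number of chain-elongation rounds + which rounds
# receive a methyl group), e.g. 5-MOA synthases methylate only round 1 while
# the anhydrosclerotinin B synthase AsbPKS methylates rounds 2 and 3.

#' Construct a methylation pattern
#'
#' @param n_extensions Number of chain-elongation rounds (>= 1); a
#'   pentaketide built from an acetyl starter has 4.
#' @param methylated_rounds Integer vector of 1-based round indices that
#'   receive a methyl group; must be a subset of `1:n_extensions`. May be
#'   empty.
#' @return Object of class `methylation_pattern`.
#' @export
#' @examples
#' methylation_pattern(4, c(2, 3))  # pentaketide methylated in rounds 2+3
methylation_pattern <- function(n_extensions, methylated_rounds = integer()) {
  n_extensions <- as.integer(n_extensions)
  methylated_rounds <- sort(unique(as.integer(methylated_rounds)))
  stopifnot(length(n_extensions) == 1L, !is.na(n_extensions))
  if (n_extensions < 1L) stop("n_extensions must be >= 1")
  if (length(methylated_rounds) > 0L &&
      (min(methylated_rounds) < 1L || max(methylated_rounds) > n_extensions)) {
    stop("methylated_rounds must be a subset of 1..n_extensions")
  }
  structure(list(n_extensions = n_extensions,
                 methylated_rounds = methylated_rounds),
            class = "methylation_pattern")
}

#' @export
format.methylation_pattern <- function(x, ...) {
  sprintf("%d extensions, methylated rounds {%s}", x$n_extensions,
          paste(x$methylated_rounds, collapse = ","))
}

#' @export
print.methylation_pattern <- function(x, ...) {
  cat("<methylation_pattern>", format(x), "\n")
  invisible(x)
}

# "2+3" <-> c(2L, 3L); "" encodes no methylation
parse_rounds <- function(txt) {
  txt <- trimws(txt)
  if (txt == "" || txt == "-") return(integer())
  as.integer(strsplit(txt, "+", fixed = TRUE)[[1]])
}

format_rounds <- function(rounds) {
  if (length(rounds) == 0L) return("-")
  paste(rounds, collapse = "+")
}

pattern_equal <- function(a, b) {
  a$n_extensions == b$n_extensions &&
    identical(a$methylated_rounds, b$methylated_rounds)
}

#' Load a catalog of characterized synthases
#'
#' Reads the tab-separated catalog format: `#` comment lines; a header row
#' `name  product  n_extensions  methylated_rounds  fingerprint  group`;
#' one synthase per row with `methylated_rounds` encoded like `"2+3"`
#' (`"-"` for none). Every fingerprint must have exactly one character per
#' pocket position of `ref` (17 for the packaged CitS annotation), over the
#' amino-acid alphabet plus `"-"`.
#'
#' @param path TSV file path.
#' @param ref Reference domain defining the pocket; default
#'   [cits_reference()].
#' @return A `pks_catalog`: `data.frame` with columns `name`, `product`,
#'   `n_extensions`, `methylated_rounds` (list column of integer vectors),
#'   `fingerprint`, `group`, in file order.
#' @export
#' @examples
#' cat <- packaged_catalog()
#' cat$name
load_catalog <- function(path, ref = cits_reference()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  line_no <- which(keep)
  lines <- raw[keep]
  if (length(lines) < 1L) stop("catalog file has no header row: ", path)
  need <- c("name", "product", "n_extensions", "methylated_rounds",
            "fingerprint", "group")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), need)) {
    stop("catalog header must be exactly: ", paste(need, collapse = ", "))
  }
  if (length(lines) < 2L) stop("catalog has no data rows: ", path)
  n_pocket <- nrow(ref$pocket)
  rows <- vector("list", length(lines) - 1L)
  for (k in seq_along(rows)) {
    ln <- line_no[k + 1L]
    parts <- strsplit(lines[k + 1L], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 6L) {
      stop(sprintf("catalog parse error at line %d: expected 6 fields, got %d",
                   ln, length(parts)))
    }
    parts <- trimws(parts)
    n_ext <- suppressWarnings(as.integer(parts[3L]))
    if (is.na(n_ext)) {
      stop(sprintf("catalog parse error at line %d: bad n_extensions '%s'",
                   ln, parts[3L]))
    }
    rounds <- tryCatch(parse_rounds(parts[4L]), warning = function(w) NA)
    if (anyNA(rounds)) {
      stop(sprintf("catalog parse error at line %d: bad methylated_rounds '%s'",
                   ln, parts[4L]))
    }
    pat <- tryCatch(methylation_pattern(n_ext, rounds), error = function(e) {
      stop(sprintf("catalog validation error at line %d: %s", ln,
                   conditionMessage(e)), call. = FALSE)
    })
    fp <- parts[5L]
    if (nchar(fp) != n_pocket) {
      stop(sprintf(
        "catalog validation error at line %d: fingerprint length %d != %d",
        ln, nchar(fp), n_pocket))
    }
    ch <- strsplit(fp, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), c(aa_alphabet(), "-"))
    if (length(bad) > 0L) {
      stop(sprintf(
        "catalog validation error at line %d: bad fingerprint symbol(s) %s",
        ln, paste(bad, collapse = ",")))
    }
    rows[[k]] <- data.frame(
      name = parts[1L], product = parts[2L],
      n_extensions = pat$n_extensions,
      fingerprint = fp, group = parts[6L],
      stringsAsFactors = FALSE
    )
    rows[[k]]$methylated_rounds <- list(pat$methylated_rounds)
  }
  out <- do.call(rbind, rows)
  out <- out[, need]
  class(out) <- c("pks_catalog", "data.frame")
  out
}

#' Write a catalog of characterized synthases
#'
#' Inverse of [load_catalog()]; round-trips all field values exactly.
#'
#' @param catalog A `pks_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(is.data.frame(catalog))
  rounds <- vapply(catalog$methylated_rounds, format_rounds, "")
  body <- sprintf("%s\t%s\t%d\t%s\t%s\t%s",
                  catalog$name, catalog$product, catalog$n_extensions,
                  rounds, catalog$fingerprint, catalog$group)
  writeLines(c(paste(c("name", "product", "n_extensions",
                       "methylated_rounds", "fingerprint", "group"),
                     collapse = "\t"), body), path)
  invisible(path)
}

#' The packaged catalog of characterized NR-PKSs
#'
#' Seeds the comparison set with characterized MT-carrying NR-PKSs: CitS
#' (citrinin), the DMOA synthases AusA/Trt4/AndM/NvfA, the DMOA-aldehyde
#' synthase DtbA, the 5-MOA synthase FncE, a 5-methyl-TAL synthase, PksAC,
#' and the anhydrosclerotinin B synthase AsbPKS. Fingerprint strings for
#' entries whose per-residue readout is not printed as text are provisional
#' fixture rows that enforce the documented facts: Phe at the CitS-2101 slot
#' in DMOA synthases and DtbA versus Leu in 5-MOA and 5-methyl-TAL
#' synthases; nonpolar residues at the CitS-2094 slot in all characterized
#' synthases except AsbPKS, which carries Glu there. Edit the TSV (see
#' [write_catalog()]) to refine entries.
#'
#' @param ref Reference domain; default [cits_reference()].
#' @return A `pks_catalog`.
#' @export
packaged_catalog <- function(ref = cits_reference()) {
  path <- system.file("extdata", "known_synthases.tsv",
                      package = "pksmine", mustWork = TRUE)
  load_catalog(path, ref)
}

# pattern of catalog row i as a methylation_pattern object
catalog_pattern <- function(catalog, i) {
  methylation_pattern(catalog$n_extensions[i], catalog$methylated_rounds[[i]])
}
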