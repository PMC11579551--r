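# Synthetic fixtures: deterministic generators of background sequence,
# MT-domain variants with prescribed pocket residues, multidomain PKS
# proteins with planted domains, and synthetic catalogs. These provide the
# ground truth the locator / fingerprint / miner chain is tested against.
# All generators are pure functions of (parameters, seed).

# deterministic ancestor sequences the seed alignments diversify;
# the MT ancestor is the packaged reference itself
.family_lengths <- c(SAT = 150L, KS = 180L, AT = 150L, PT = 140L, ACP = 70L)
.family_seeds <- c(SAT = 7001L, KS = 7002L, AT = 7003L, PT = 7004L,
                   ACP = 7005L)

#' Deterministic ancestor sequence of a domain family
#'
#' SAT/KS/AT/PT/ACP ancestors are fixed background draws (one internal seed
#' per family); the MT ancestor is the reference MT-domain sequence. These
#' are the sequences the packaged seed alignments and the planted blocks of
#' [synth_pks()] derive from.
#'
#' @param family One of `"SAT"`, `"KS"`, `"AT"`, `"PT"`, `"ACP"`, `"MT"`.
#' @param ref Reference domain used for the MT ancestor.
#' @return Amino-acid string.
#' @export
family_ancestor <- function(family, ref = cits_reference()) {
  family <- match.arg(family, DOMAIN_FAMILIES)
  if (family == "MT") return(ref$sequence)
  generate_background(.family_lengths[[family]], .family_seeds[[family]])
}

#' Generate random background protein sequence
#'
#' i.i.d. draws from [aa_background()]; identical output for identical
#' seed.
#'
#' @param length Nonnegative sequence length.
#' @param seed Integer seed.
#' @return Amino-acid string of the requested length.
#' @export
generate_background <- function(length, seed) {
  stopifnot(is.numeric(length), length(length) == 1L)
  if (length < 0) stop("length must be nonnegative")
  length <- as.integer(length)
  if (length == 0L) return("")
  with_seed(seed, {
    paste(sample(aa_alphabet(), length, replace = TRUE,
                 prob = aa_background()), collapse = "")
  })
}

# substitute characters at the given indices with random different residues
.mutate_sites <- function(ch, idx) {
  for (i in idx) {
    repeat {
      r <- sample(aa_alphabet(), 1L, prob = aa_background())
      if (r != ch[i]) break
    }
    ch[i] <- r
  }
  ch
}

#' Synthesize an MT-domain variant with prescribed pocket residues
#'
#' Copies the reference sequence, overwrites the pocket positions with the
#' prescribed residues, then applies random substitutions to non-pocket
#' sites at the given rate.
#'
#' @param ref A [reference_domain()].
#' @param prescribed Residue string, one amino acid per pocket position.
#' @param substitution_rate Per-site substitution probability for
#'   non-pocket sites, in `[0, 0.3]`.
#' @param seed Integer seed.
#' @param name Name recorded in the truth record.
#' @return List with `sequence` and `truth` (name, planted `fingerprint`,
#'   `seed`, `substitution_rate`).
#' @export
synth_mt_variant <- function(ref, prescribed, substitution_rate = 0,
                             seed = 1L, name = "mt_variant") {
  stopifnot(inherits(ref, "reference_domain"))
  pk_n <- nrow(ref$pocket)
  if (nchar(prescribed) != pk_n) {
    stop("prescribed fingerprint must have ", pk_n, " characters")
  }
  pch <- strsplit(prescribed, "", fixed = TRUE)[[1]]
  if (!all(pch %in% aa_alphabet())) {
    stop("prescribed fingerprint must use amino-acid letters only")
  }
  if (substitution_rate < 0 || substitution_rate > 0.3) {
    stop("substitution_rate must lie in [0, 0.3]")
  }
  ch <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  pk_idx <- ref$pocket$cits_position - ref$offset + 1L
  ch[pk_idx] <- pch
  seq <- with_seed(seed, {
    other <- setdiff(seq_along(ch), pk_idx)
    hit <- other[stats::runif(length(other)) < substitution_rate]
    paste(.mutate_sites(ch, hit), collapse = "")
  })
  list(sequence = seq,
       truth = list(name = name, fingerprint = prescribed, seed = seed,
                    substitution_rate = substitution_rate))
}

#' Synthesize a multidomain PKS protein with planted domains
#'
#' Concatenates per-family ancestor blocks (the MT block carrying the
#' prescribed pocket residues) separated by background linkers of seeded
#' length 20-60, with leading and trailing linkers. Point substitutions at
#' `substitution_rate` are applied to domain blocks (sparing pocket sites).
#' The truth record lists every planted interval.
#'
#' @param architecture Ordered character vector of families, e.g.
#'   `c("SAT","KS","AT","PT","ACP","MT")`.
#' @param mt_prescription Pocket residue string planted in the MT block
#'   (default: the reference self-fingerprint).
#' @param seed Integer seed.
#' @param substitution_rate Per-site substitution probability inside domain
#'   blocks.
#' @param ref Reference domain.
#' @param name Protein name in the truth record.
#' @return List with `sequence` and `truth` (`name`, `domains` data.frame
#'   of family/start/end, `fingerprint`, `seed`, `substitution_rate`).
#' @export
synth_pks <- function(architecture, mt_prescription = NULL, seed = 1L,
                      substitution_rate = 0, ref = cits_reference(),
                      name = "synthetic_pks") {
  if (length(architecture) < 1L) stop("architecture must be non-empty")
  bad <- setdiff(architecture, DOMAIN_FAMILIES)
  if (length(bad) > 0L) {
    stop("unsupported domain family: ", paste(bad, collapse = ", "))
  }
  if (is.null(mt_prescription)) {
    mt_prescription <- paste(ref$pocket$reference_residue, collapse = "")
  }
  if (substitution_rate < 0 || substitution_rate > 0.3) {
    stop("substitution_rate must lie in [0, 0.3]")
  }
  pk_idx <- ref$pocket$cits_position - ref$offset + 1L
  with_seed(seed, {
    pieces <- character(0)
    fam <- character(0)
    starts <- integer(0)
    ends <- integer(0)
    pos <- 0L
    linker <- function() {
      len <- sample(20:60, 1L)
      paste(sample(aa_alphabet(), len, replace = TRUE,
                   prob = aa_background()), collapse = "")
    }
    add <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add(linker())
    for (f in architecture) {
      block <- family_ancestor(f, ref)
      ch <- strsplit(block, "", fixed = TRUE)[[1]]
      if (f == "MT") {
        ch[pk_idx] <- strsplit(mt_prescription, "", fixed = TRUE)[[1]]
        protect <- pk_idx
      } else {
        protect <- integer(0)
      }
      if (substitution_rate > 0) {
        free <- setdiff(seq_along(ch), protect)
        hit <- free[stats::runif(length(free)) < substitution_rate]
        ch <- .mutate_sites(ch, hit)
      }
      fam <- c(fam, f)
      starts <- c(starts, pos + 1L)
      add(paste(ch, collapse = ""))
      ends <- c(ends, pos)
      add(linker())
    }
    list(
      sequence = paste(pieces, collapse = ""),
      truth = list(
        name = name,
        domains = data.frame(family = fam, start = starts, end = ends,
                             stringsAsFactors = FALSE),
        fingerprint = mt_prescription,
        seed = seed,
        substitution_rate = substitution_rate
      )
    )
  })
}

#' Synthesize a catalog with grouped fingerprints and matching MT sequences
#'
#' Each group contributes `count` members whose fingerprints equal the
#' group fingerprint perturbed independently at each slot with probability
#' `divergence`; perturbations stay within the residue's chemistry class
#' (conservative substitutions), so group identity is carried by exact
#' residues while chemistry classes stay stable. Matching MT-domain
#' sequences are generated with [synth_mt_variant()].
#'
#' @param groups List of group specs: each a list with `name`, `pattern`
#'   (a [methylation_pattern()]), `count` (>= 1) and `fingerprint`.
#' @param divergence Per-slot perturbation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param ref Reference domain.
#' @param mt_substitution_rate Non-pocket substitution rate of the emitted
#'   MT sequences (default 0.02).
#' @return List with `catalog` (a `pks_catalog`) and `sequences` (named
#'   character vector of member MT domains).
#' @export
synth_catalog <- function(groups, divergence = 0.05, seed = 1L,
                          ref = cits_reference(),
                          mt_substitution_rate = 0.02) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  pk_n <- nrow(ref$pocket)
  with_seed(seed, {
    rows <- list()
    seqs <- character(0)
    for (g in groups) {
      stopifnot(!is.null(g$name), inherits(g$pattern, "methylation_pattern"),
                g$count >= 1L, nchar(g$fingerprint) == pk_n)
      base <- strsplit(g$fingerprint, "", fixed = TRUE)[[1]]
      for (m in seq_len(g$count)) {
        fp <- base
        for (k in seq_len(pk_n)) {
          if (stats::runif(1) < divergence) {
            cls <- chemistry_class(fp[k])
            pool <- setdiff(.chem_classes[[cls]], fp[k])
            if (length(pool) > 0L) fp[k] <- sample(pool, 1L)
          }
        }
        member <- sprintf("%s_%d", g$name, m)
        fp_str <- paste(fp, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          name = member, product = g$name,
          n_extensions = g$pattern$n_extensions,
          fingerprint = fp_str, group = g$name,
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$methylated_rounds <-
          list(g$pattern$methylated_rounds)
        v <- synth_mt_variant(ref, fp_str,
                              substitution_rate = mt_substitution_rate,
                              seed = sample.int(.Machine$integer.max, 1L),
                              name = member)
        seqs[[member]] <- v$sequence
      }
    }
    catalog <- do.call(rbind, rows)
    catalog <- catalog[, c("name", "product", "n_extensions",
                           "methylated_rounds", "fingerprint", "group")]
    class(catalog) <- c("pks_catalog", "data.frame")
    list(catalog = catalog, sequences = seqs)
  })
}

#' Build a synthetic seed alignment for a domain family
#'
#' First row is the family ancestor; the remaining rows carry independent
#' point substitutions at `substitution_rate` (no indels, so every column
#' is a match column). Used to generate the packaged seed fixtures and to
#' build throwaway profiles in tests.
#'
#' @param family Domain family.
#' @param n_rows Number of rows (>= 2).
#' @param substitution_rate Per-site substitution probability of non-ancestor
#'   rows.
#' @param seed Integer seed.
#' @param ref Reference domain (for the MT ancestor).
#' @return A [seed_alignment()].
#' @export
make_seed_alignment <- function(family, n_rows = 8L,
                                substitution_rate = 0.1, seed = 1L,
                                ref = cits_reference()) {
  stopifnot(n_rows >= 2L)
  anc <- family_ancestor(family, ref)
  ch0 <- strsplit(anc, "", fixed = TRUE)[[1]]
  rows <- with_seed(seed, {
    c(anc, vapply(seq_len(n_rows - 1L), function(i) {
      hit <- which(stats::runif(length(ch0)) < substitution_rate)
      paste(.mutate_sites(ch0, hit), collapse = "")
    }, ""))
  })
  names(rows) <- sprintf("%s_seed_%02d", family, seq_len(n_rows))
  seed_alignment(family, rows)
}
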