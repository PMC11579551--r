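# End-to-end mining pipeline: FASTA in -> domain scan -> architecture
# filter -> MT extraction -> fingerprints -> catalog comparison -> trees /
# logos -> ranked novelty report.

#' Mining configuration
#'
#' @param reference A [reference_domain()]; default the packaged CitS
#'   annotation.
#' @param catalog A `pks_catalog`; default [packaged_catalog()].
#' @param profiles Named list of `domain_profile`s; default
#'   [packaged_profiles()].
#' @param scan_threshold Minimum hit score in bits.
#' @param w_class Chemistry-change weight of the novelty score.
#' @param nj_cap Jukes-Cantor saturation cap.
#' @param logo_correction Apply the small-sample logo correction.
#' @param ks_tree Also build a KS-domain tree and report its
#'   Robinson-Foulds distance to the MT tree.
#' @param seed Master seed; all pipeline randomness flows from it.
#' @return Object of class `mining_config`.
#' @export
mining_config <- function(reference = cits_reference(),
                          catalog = packaged_catalog(reference),
                          profiles = packaged_profiles(),
                          scan_threshold = 40,
                          w_class = 2,
                          nj_cap = 10,
                          logo_correction = TRUE,
                          ks_tree = TRUE,
                          seed = 1L) {
  stopifnot(inherits(reference, "reference_domain"),
            is.data.frame(catalog), is.list(profiles),
            scan_threshold > 0, w_class >= 0, nj_cap > 0)
  structure(list(reference = reference, catalog = catalog,
                 profiles = profiles, scan_threshold = scan_threshold,
                 w_class = w_class, nj_cap = nj_cap,
                 logo_correction = isTRUE(logo_correction),
                 ks_tree = isTRUE(ks_tree), seed = as.integer(seed)),
            class = "mining_config")
}

#' Read a mining configuration file
#'
#' Simple key-value text format (one `key value` or `key = value` per line,
#' `#` comments) mirroring the [mining_config()] arguments: `reference`,
#' `catalog` and `seeds` take file paths; `scan_threshold`, `w_class`,
#' `nj_cap`, `seed` numbers; `logo_correction`, `ks_tree` true/false.
#' Unset keys keep their defaults.
#'
#' @param path Config file path.
#' @return A `mining_config`.
#' @export
read_mining_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(sub("=", " ", ln, fixed = TRUE), "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    kv[[parts[1L]]] <- paste(parts[-1L], collapse = " ")
  }
  ref <- if (!is.null(kv$reference)) read_reference(kv$reference)
         else cits_reference()
  profiles <- if (!is.null(kv$seeds)) {
    files <- list.files(kv$seeds, pattern = "\\.afa$", full.names = TRUE)
    lapply(setNames(files, sub("_.*$", "", basename(files))),
           function(f) build_profile(read_seed_alignment(f)))
  } else packaged_profiles()
  mining_config(
    reference = ref,
    catalog = if (!is.null(kv$catalog)) load_catalog(kv$catalog, ref)
              else packaged_catalog(ref),
    profiles = profiles,
    scan_threshold = if (!is.null(kv$scan_threshold))
      as.numeric(kv$scan_threshold) else 40,
    w_class = if (!is.null(kv$w_class)) as.numeric(kv$w_class) else 2,
    nj_cap = if (!is.null(kv$nj_cap)) as.numeric(kv$nj_cap) else 10,
    logo_correction = if (!is.null(kv$logo_correction))
      tolower(kv$logo_correction) %in% c("true", "1", "yes") else TRUE,
    ks_tree = if (!is.null(kv$ks_tree))
      tolower(kv$ks_tree) %in% c("true", "1", "yes") else TRUE,
    seed = if (!is.null(kv$seed)) as.integer(kv$seed) else 1L
  )
}

#' Mine candidate PKS proteins
#'
#' Runs the full chain for each input protein: profile scan, architecture
#' classification and NR-PKS flag, MT extraction (envelope + 30 residues),
#' active-site fingerprint, and novelty report against the catalog.
#' Globally it builds a reference-anchored MSA and Neighbor-Joining tree of
#' the extracted MT domains (when at least two were found), optionally a KS
#' tree with its Robinson-Foulds distance to the MT tree, and per-group
#' catalog logos. Deterministic given the config seed.
#'
#' @param input Path to a protein FASTA file, or a named character vector
#'   of amino-acid strings.
#' @param config A [mining_config()].
#' @return Object of class `mining_result`: `candidates` (summary
#'   `data.frame` in ranked order), `reports` (ranked list of
#'   [novelty_report()]s), `hits`, `fingerprints`, `mt_msa`, `mt_tree`,
#'   `ks_tree`, `rf_distance`, `logos`, `seed`, `schema_version`.
#' @export
mine <- function(input, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  seqs <- if (is.character(input) && length(input) == 1L &&
              file.exists(input)) read_fasta(input) else input
  if (!is.character(seqs) || length(seqs) < 1L) {
    stop("input must be a FASTA path or a named character vector")
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ref <- config$reference

  with_seed(config$seed, {
    per <- lapply(names(seqs), function(nm) {
      protein <- seqs[[nm]]
      hits <- scan_domains(protein, config$profiles,
                           threshold_bits = config$scan_threshold)
      arch <- tryCatch(classify_architecture(hits), error = function(e) {
        list(architecture = "ambiguous", nr_pks = FALSE)
      })
      mt_hits <- hits[hits$family == "MT", , drop = FALSE]
      ks_hits <- hits[hits$family == "KS", , drop = FALSE]
      out <- list(name = nm, hits = hits, architecture = arch$architecture,
                  nr_pks = arch$nr_pks, mt_domain = NULL, ks_domain = NULL,
                  fingerprint = NULL, report = NULL)
      if (nrow(mt_hits) > 0L) {
        best <- mt_hits[which.max(mt_hits$score), , drop = FALSE]
        out$mt_domain <- extract_mt_domain(protein, best)
        out$fingerprint <- extract_fingerprint(out$mt_domain, ref,
                                               source_name = nm)
        out$report <- novelty_report(out$fingerprint, config$catalog,
                                     name = nm, w_class = config$w_class,
                                     ref = ref)
      }
      if (nrow(ks_hits) > 0L) {
        best_ks <- ks_hits[which.max(ks_hits$score), , drop = FALSE]
        out$ks_domain <- substr(protein, best_ks$start, best_ks$end)
      }
      out
    })
    names(per) <- names(seqs)

    with_mt <- Filter(function(x) !is.null(x$mt_domain), per)
    if (length(with_mt) == 0L) {
      stop(structure(class = c("pksmine_no_mt", "error", "condition"),
                     list(message = "no MT domain found in any input protein",
                          call = sys.call(-1))))
    }

    reports <- rank_candidates(lapply(with_mt, `[[`, "report"))
    mt_seqs <- vapply(with_mt, `[[`, "", "mt_domain")
    mt_msa <- NULL
    mt_tree <- NULL
    if (length(mt_seqs) >= 2L) {
      mt_msa <- star_msa(mt_seqs, ref)
      mt_tree <- nj_tree(dist_jc(mt_msa, cap = config$nj_cap))
    }
    ks_tree <- NULL
    rf <- NULL
    if (config$ks_tree) {
      ks_seqs <- vapply(Filter(function(x) !is.null(x$ks_domain), per),
                        `[[`, "", "ks_domain")
      ks_seqs <- ks_seqs[intersect(names(ks_seqs), names(mt_seqs))]
      if (length(ks_seqs) >= 3L && length(ks_seqs) == length(mt_seqs)) {
        ks_msa <- star_msa(ks_seqs, family_ancestor("KS", ref))
        ks_tree <- nj_tree(dist_jc(ks_msa, cap = config$nj_cap))
        if (!is.null(mt_tree)) rf <- robinson_foulds(mt_tree, ks_tree)
      }
    }

    logos <- lapply(split(config$catalog$fingerprint, config$catalog$group),
                    build_logo,
                    correct_small_sample = config$logo_correction)
    cand_fps <- vapply(reports, `[[`, "", "fingerprint")
    logos[["candidates"]] <- build_logo(
      cand_fps, correct_small_sample = config$logo_correction)

    candidates <- data.frame(
      name = vapply(reports, `[[`, "", "name"),
      architecture = vapply(reports, function(r) per[[r$name]]$architecture, ""),
      nr_pks = vapply(reports, function(r) per[[r$name]]$nr_pks, logical(1)),
      fingerprint = cand_fps,
      score = vapply(reports, `[[`, numeric(1), "score"),
      min_distance = vapply(reports, `[[`, integer(1), "min_distance"),
      nearest = vapply(reports, function(r) paste(r$nearest, collapse = ","), ""),
      predicted_pattern = vapply(reports, `[[`, "", "predicted_pattern"),
      novel_positions = vapply(reports, function(r)
        paste(r$novel_positions, collapse = ","), ""),
      class_change_positions = vapply(reports, function(r)
        paste(r$class_change_positions, collapse = ","), ""),
      stringsAsFactors = FALSE, row.names = NULL
    )

    structure(list(candidates = candidates, reports = reports,
                   hits = lapply(per, `[[`, "hits"),
                   fingerprints = lapply(with_mt, `[[`, "fingerprint"),
                   mt_msa = mt_msa, mt_tree = mt_tree, ks_tree = ks_tree,
                   rf_distance = rf, logos = logos, seed = config$seed,
                   schema_version = "1.0"),
              class = "mining_result")
  })
}

#' Write a mining result bundle to disk
#'
#' Writes `report.json` (schema-version-stamped full report),
#' `ranked.tsv`, `fingerprints.tsv`, `mt_tree.nwk` (when built),
#' `ks_tree.nwk` + `rf.txt` (when built), and one `logos/<group>.tsv` per
#' logo.
#'
#' @param result A [mine()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
report_writer <- function(result, out_dir) {
  stopifnot(inherits(result, "mining_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  report <- list(
    schema_version = result$schema_version,
    seed = result$seed,
    candidates = lapply(result$reports, function(r) {
      list(name = r$name, fingerprint = r$fingerprint,
           novel_positions = as.integer(r$novel_positions),
           class_change_positions = as.integer(r$class_change_positions),
           min_distance = r$min_distance, nearest = as.character(r$nearest),
           predicted_pattern = r$predicted_pattern, score = r$score)
    }),
    rf_distance = if (is.null(result$rf_distance)) NULL
                  else result$rf_distance
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  utils::write.table(result$candidates, file.path(out_dir, "ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fingerprints(result$fingerprints,
                     file.path(out_dir, "fingerprints.tsv"))
  if (!is.null(result$mt_tree)) {
    write_newick(result$mt_tree, file.path(out_dir, "mt_tree.nwk"))
  }
  if (!is.null(result$ks_tree)) {
    write_newick(result$ks_tree, file.path(out_dir, "ks_tree.nwk"))
    if (!is.null(result$rf_distance)) {
      writeLines(as.character(result$rf_distance),
                 file.path(out_dir, "rf.txt"))
    }
  }
  logo_dir <- file.path(out_dir, "logos")
  dir.create(logo_dir, showWarnings = FALSE)
  for (g in names(result$logos)) {
    write_logo(result$logos[[g]],
               file.path(logo_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", g),
                                          ".tsv")))
  }
  invisible(out_dir)
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("<mining_result> %d candidate(s), seed %d\n",
              nrow(x$candidates), x$seed))
  print(utils::head(x$candidates[, c("name", "architecture", "score",
                                     "min_distance", "predicted_pattern")],
                    10L))
  invisible(x)
}
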