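test_that("profile scores follow the log-odds closed form", {
  q <- aa_background()
  seed <- seed_alignment("MT", c("ACD", "ACD"))
  prof <- build_profile(seed, pseudocount_weight = 0)
  expect_identical(prof$length, 3L)
  expect_equal(unname(prof$scores[1, "A"]), log2(1 / q[["A"]]),
               tolerance = 1e-10)
  expect_equal(unname(prof$scores[2, "C"]), log2(1 / q[["C"]]),
               tolerance = 1e-10)
  # huge pseudocount shrinks every score toward 0
  prof_inf <- build_profile(seed, pseudocount_weight = 1e6)
  expect_lt(max(abs(prof_inf$scores)), 1e-4)
})

test_that("profile frequencies match a brute-force count oracle", {
  rows <- c("ACDK", "AADK", "ACEK", "GCDW")
  seed <- seed_alignment("KS", rows)
  alpha <- 0.7
  prof <- build_profile(seed, pseudocount_weight = alpha)
  q <- aa_background()
  mat <- do.call(rbind, strsplit(rows, ""))
  for (col in 1:4) {
    for (aa in aa_alphabet()) {
      f <- mean(mat[, col] == aa)  # independent count
      expect_equal(unname(prof$scores[col, aa]),
                   log2((f + alpha * q[[aa]]) / ((1 + alpha) * q[[aa]])),
                   tolerance = 1e-10)
    }
  }
})

test_that("majority-gap seed columns are dropped as inserts", {
  rows <- c("A-CD", "A-CD", "AWCD", "A--D")
  prof <- build_profile(seed_alignment("AT", rows))
  # column 2 has 3/4 gaps -> insert; column 3 has 1/4 -> match
  expect_identical(prof$length, 3L)
  expect_identical(prof$match_cols, c(1L, 3L, 4L))
  expect_error(seed_alignment("AT", "ACD"), ">= 2 rows")
})

test_that("scan finds a planted consensus and ignores plain background", {
  profs <- packaged_profiles()
  cons <- profile_consensus(profs$ACP)
  protein <- paste0(generate_background(100, seed = 21), cons,
                    generate_background(80, seed = 22))
  hits <- scan_protein(protein, profs$ACP)
  expect_identical(nrow(hits), 1L)
  expect_lte(abs(hits$start - 101L), 10L)
  expect_lte(abs(hits$end - (100L + nchar(cons))), 10L)

  # no planted domain: nothing above threshold
  bg <- generate_background(400, seed = 23)
  expect_identical(nrow(scan_protein(bg, profs$ACP)), 0L)

  # two planted copies -> two disjoint envelopes
  protein2 <- paste0(generate_background(60, seed = 24), cons,
                     generate_background(50, seed = 25), cons,
                     generate_background(40, seed = 26))
  hits2 <- scan_protein(protein2, profs$ACP)
  expect_identical(nrow(hits2), 2L)
  hits2 <- hits2[order(hits2$start), ]
  expect_lt(hits2$end[1], hits2$start[2])

  expect_error(scan_protein("ACDXB", profs$ACP), "X")
})

test_that("planted consensus outscores equal-length background windows", {
  profs <- packaged_profiles()
  for (fam in c("ACP", "PT")) {
    cons <- profile_consensus(profs[[fam]])
    s_cons <- scan_protein(cons, profs[[fam]], threshold_bits = 1)$score[1]
    bg <- generate_background(nchar(cons), seed = 31 + match(fam, names(profs)))
    s_bg <- scan_protein(bg, profs[[fam]], threshold_bits = -Inf,
                         max_hits = 1L)
    s_bg <- if (nrow(s_bg) == 0L) 0 else s_bg$score[1]
    expect_gt(s_cons, s_bg)
  }
})

test_that("MT extraction applies the 30-residue C-terminal extension", {
  hit <- data.frame(family = "MT", start = 101L, end = 300L, score = 50,
                    extended_end = 330L)
  protein <- generate_background(400, seed = 41)
  out <- extract_mt_domain(protein, hit)
  expect_identical(nchar(out), 230L)
  expect_identical(out, substr(protein, 101, 330))

  short <- substr(protein, 1, 320)
  expect_identical(nchar(extract_mt_domain(short, hit)), 220L)

  hit_all <- data.frame(family = "MT", start = 1L, end = 400L, score = 50,
                        extended_end = 400L)
  expect_identical(extract_mt_domain(protein, hit_all), protein)

  ks_hit <- data.frame(family = "KS", start = 1L, end = 100L, score = 50,
                       extended_end = 100L)
  expect_error(extract_mt_domain(protein, ks_hit), "MT hit")
})

test_that("architecture string is ordered by start and flags NR-PKSs", {
  mk <- function(fams, starts, ends) {
    data.frame(family = fams, start = starts, end = ends,
               score = 50, extended_end = ends)
  }
  h <- mk(c("SAT", "KS", "AT", "PT", "ACP", "MT"),
          c(1, 200, 400, 600, 800, 900) + 0L,
          c(150, 380, 550, 750, 870, 1200) + 0L)
  out <- classify_architecture(h)
  expect_identical(out$architecture, "SAT-KS-AT-PT-ACP-MT")
  expect_true(out$nr_pks)

  # input order must not matter
  perm <- classify_architecture(h[sample(nrow(h)), ])
  expect_identical(perm$architecture, out$architecture)

  partial <- classify_architecture(mk(c("KS", "AT"), c(1L, 300L),
                                      c(200L, 500L)))
  expect_identical(partial$architecture, "KS-AT")
  expect_false(partial$nr_pks)

  expect_error(
    classify_architecture(mk(c("KS", "AT"), c(1L, 100L), c(200L, 300L))),
    "ambiguous")
})

test_that("scan recovers planted domains across mutated replicates", {
  profs <- packaged_profiles()
  ref <- cits_reference()
  arch <- c("SAT", "KS", "AT", "PT", "ACP", "MT")
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    p <- synth_pks(arch, seed = 100L + r, substitution_rate = 0.1,
                   ref = ref)
    hits <- scan_domains(p$sequence, profs)
    expect_identical(hits$family, arch)
    truth_mid <- (p$truth$domains$start + p$truth$domains$end) / 2
    hit_mid <- (hits$start + hits$end) / 2
    expect_true(all(abs(hit_mid - truth_mid) <= 15))
    # extraction never exceeds sequence bounds
    mt <- hits[hits$family == "MT", ]
    expect_lte(mt$extended_end, nchar(p$sequence))
    expect_identical(
      nchar(extract_mt_domain(p$sequence, mt)),
      as.integer(min(mt$end + 30L, nchar(p$sequence)) - mt$start + 1L))
  }
})
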