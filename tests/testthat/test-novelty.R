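test_that("chemistry classes follow the fixed partition", {
  expect_identical(chemistry_class("M"), "nonpolar")
  expect_identical(chemistry_class("E"), "acidic")
  expect_identical(chemistry_class("H"), "basic")
  expect_identical(chemistry_class("S"), "polar")
  expect_identical(chemistry_class("-"), "gap")
  expect_error(chemistry_class("B"), "unknown residue")
  # the partition covers the whole alphabet exactly once
  expect_setequal(unique(chemistry_class(aa_alphabet())),
                  c("nonpolar", "polar", "acidic", "basic"))
})

test_that("position novelty flags unseen residues and chemistry changes", {
  cat <- packaged_catalog()
  ref <- cits_reference()
  # a catalog member is never novel against its own catalog
  pn <- position_novelty(cat$fingerprint[cat$name == "CitS"], cat, ref)
  expect_length(pn$novel_positions, 0)
  expect_length(pn$class_change_positions, 0)

  # drop AsbPKS to re-enact the discovery: E at the 2094 slot is then both
  # unseen and chemistry-changing (catalog all nonpolar there)
  known <- cat[cat$name != "AsbPKS", ]
  class(known) <- class(cat)
  asb_like <- fp_sub(cat$fingerprint[cat$name == "CitS"], 11, "E")
  pn2 <- position_novelty(asb_like, known, ref)
  expect_true(2094L %in% pn2$novel_positions)
  expect_true(2094L %in% pn2$class_change_positions)

  # L at the 2101 slot is not flagged: the catalog holds both F and L there
  l_at_2101 <- fp_sub(cat$fingerprint[cat$name == "CitS"], 13, "L")
  pn3 <- position_novelty(l_at_2101, known, ref)
  expect_false(2101L %in% pn3$novel_positions)

  # class-change positions are always a subset of novel positions
  expect_true(all(pn2$class_change_positions %in% pn2$novel_positions))
  expect_error(position_novelty(asb_like, cat[0, ], ref), "empty")
})

test_that("novelty score weights chemistry changes", {
  cat <- packaged_catalog()
  known <- cat[cat$name != "AsbPKS", ]
  class(known) <- class(cat)
  base <- cat$fingerprint[cat$name == "CitS"]
  expect_identical(novelty_score(base, known), 0)
  # slot 11 carries M and L in the known catalog; I is unseen but nonpolar
  same_class <- fp_sub(base, 11, "I")
  expect_identical(novelty_score(same_class, known, w_class = 2), 1)
  # E is unseen and acidic where only nonpolar occurs
  cross_class <- fp_sub(base, 11, "E")
  expect_identical(novelty_score(cross_class, known, w_class = 2), 3)
  expect_identical(novelty_score(cross_class, known, w_class = 0), 1)
})

test_that("pattern prediction transfers the nearest neighbor", {
  cat <- packaged_catalog()
  # exact match: a DMOA row predicts its own pattern
  pred <- predict_pattern(cat$fingerprint[cat$name == "AusA"], cat)
  expect_false(pred$ambiguous)
  expect_identical(pred$min_distance, 0L)
  expect_identical(pred$pattern$methylated_rounds, c(1L, 2L))

  # one substitution from a unique nearest row
  near <- fp_sub(cat$fingerprint[cat$name == "AsbPKS"], 3, "A")
  pred2 <- predict_pattern(near, cat)
  expect_identical(pred2$min_distance, 1L)
  expect_identical(pred2$nearest, "AsbPKS")
  expect_identical(pred2$pattern$methylated_rounds, c(2L, 3L))

  # equidistant rows with different patterns -> ambiguous with tied set
  toy <- cat[cat$name %in% c("CitS", "AusA"), ]
  class(toy) <- class(cat)
  # CitS and AusA fingerprints differ at slots 11 and 13; a hybrid carrying
  # one residue from each sits at distance 1 from both
  hybrid <- fp_sub(toy$fingerprint[toy$name == "CitS"], 13, "F")
  d <- vapply(toy$fingerprint, fingerprint_distance, integer(1), hybrid)
  expect_true(all(d == 1L))
  pred3 <- predict_pattern(hybrid, toy)
  expect_true(pred3$ambiguous)
  expect_setequal(pred3$nearest, c("CitS", "AusA"))
})

test_that("catalog members score zero and predict their own pattern", {
  cat <- packaged_catalog()
  for (i in seq_len(nrow(cat))) {
    rep <- novelty_report(cat$fingerprint[i], cat, name = cat$name[i])
    expect_identical(rep$score, 0)
    expect_identical(rep$min_distance, 0L)
    expect_true(cat$name[i] %in% rep$nearest)
  }
})

test_that("growing the catalog never increases novelty scores", {
  cat <- packaged_catalog()
  set.seed(71)
  for (k in 1:10) {
    fp <- paste(sample(aa_alphabet(), 17, replace = TRUE), collapse = "")
    sub <- cat[sample(nrow(cat), 4), ]
    class(sub) <- class(cat)
    expect_gte(novelty_score(fp, sub), novelty_score(fp, cat))
  }
})

test_that("ranking orders by score, then distance, then name", {
  cat <- packaged_catalog()
  known <- cat[cat$name != "AsbPKS", ]
  class(known) <- class(cat)
  base <- cat$fingerprint[cat$name == "CitS"]
  reports <- list(
    novelty_report(fp_sub(base, 11, "E"), known, name = "cross"),
    novelty_report(base, known, name = "member"),
    novelty_report(fp_sub(base, 11, "I"), known, name = "same_class")
  )
  ranked <- rank_candidates(reports)
  expect_identical(vapply(ranked, `[[`, "", "name"),
                   c("cross", "same_class", "member"))
  # stable under permutation of the input
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    expect_identical(
      vapply(rank_candidates(reports[perm]), `[[`, "", "name"),
      c("cross", "same_class", "member"))
  }
  expect_identical(rank_candidates(reports[1]), reports[1])
})

test_that("cross-class novelty outranks within-class novelty on synthetic catalogs", {
  ref <- cits_reference()
  for (s in 1:3) {
    syn <- synth_catalog(four_group_spec(), divergence = 0.05,
                         seed = 500L + s, ref = ref)
    base <- four_group_spec()[[1]]$fingerprint
    cross <- novelty_report(fp_sub(base, 11, "E"), syn$catalog,
                            name = "cross", ref = ref)
    within <- lapply(c(1, 5, 12), function(k) {
      # within-class (nonpolar) substitutions at other nonpolar slots
      novelty_report(fp_sub(base, k, "G"), syn$catalog,
                     name = paste0("within", k), ref = ref)
    })
    ranked <- rank_candidates(c(list(cross), within))
    expect_identical(ranked[[1]]$name, "cross")
  }
})
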