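test_that("star MSA merges members on reference columns", {
  ref <- cits_reference()
  two <- c(a = ref$sequence, b = ref$sequence)
  msa <- star_msa(two, ref)
  expect_identical(unname(msa$rows), unname(two))  # no gaps introduced

  # one member with an insertion forces a gap block in the other rows
  k <- 80L
  with_ins <- c(a = ref$sequence,
                b = paste0(substr(ref$sequence, 1, k), "WWW",
                           substr(ref$sequence, k + 1, nchar(ref$sequence))))
  msa2 <- star_msa(with_ins, ref)
  expect_identical(nchar(msa2$rows[["a"]]), nchar(ref$sequence) + 3L)
  expect_identical(nchar(gsub("[^-]", "", msa2$rows[["a"]])), 3L)
  # degapping reproduces the inputs (checked internally, re-assert here)
  expect_identical(gsub("-", "", msa2$rows[["b"]]), unname(with_ins["b"]))
})

test_that("p-distance counts mismatches over mutually non-gap columns", {
  msa <- structure(list(
    names = c("x", "y", "z"),
    rows = c(x = "ACDEFGHIKL", y = "ACDEFGHIKV", z = "----------"),
    ref_columns = 1:10), class = "star_msa")
  expect_identical(p_distance(msa, "x", "x"), 0)
  expect_identical(p_distance(msa, "x", "y"), 0.1)
  expect_error(p_distance(msa, "x", "z"), "no mutually non-gap")

  # random pairs against an exhaustive per-column oracle
  set.seed(61)
  for (k in 1:5) {
    a <- sample(c(aa_alphabet(), "-"), 60, replace = TRUE)
    b <- sample(c(aa_alphabet(), "-"), 60, replace = TRUE)
    m <- structure(list(names = c("a", "b"),
                        rows = c(a = paste(a, collapse = ""),
                                 b = paste(b, collapse = "")),
                        ref_columns = 1:60), class = "star_msa")
    shared <- a != "-" & b != "-"
    expect_equal(p_distance(m, "a", "b"), mean(a[shared] != b[shared]))
  }
})

test_that("protein Jukes-Cantor correction matches its closed form", {
  expect_identical(jc_distance(0), 0)
  expect_equal(jc_distance(0.5), 0.70985, tolerance = 1e-4)
  expect_equal(jc_distance(0.5), -(19 / 20) * log(1 - (20 / 19) * 0.5),
               tolerance = 1e-12)
  p <- seq(0, 0.9, by = 0.05)
  d <- jc_distance(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
  # first-order agreement near 0
  small <- seq(0.005, 0.05, by = 0.005)
  expect_true(all(abs(jc_distance(small) - small) <= small^2))
  # saturation cap
  expect_identical(jc_distance(0.97), 10)
  expect_identical(jc_distance(0.97, cap = 3), 3)
  expect_error(jc_distance(1.2), "\\[0, 1\\]")
})

test_that("NJ reconstructs additive and ultrametric test cases", {
  # additive 4-taxon matrix from tree ((A,B),(C,D)) with internal edge 2
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  el <- c(A = 1, B = 3, C = 2, D = 4)
  mid <- 2
  D["A", "B"] <- D["B", "A"] <- el["A"] + el["B"]
  D["C", "D"] <- D["D", "C"] <- el["C"] + el["D"]
  for (x in c("A", "B")) for (y in c("C", "D")) {
    D[x, y] <- D[y, x] <- el[x] + el[y] + mid
  }
  tree <- nj_tree(D)
  # topology: AB|CD split recovered and path lengths reproduce D exactly
  expect_identical(
    robinson_foulds(tree, ape::read.tree(text = "((A,B),(C,D));")), 0L)
  cop <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_equal(unname(cop), unname(D), tolerance = 1e-9)

  # 2 taxa at distance 1 -> single edge of total length 1
  D2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(D2)
  expect_identical(sum(t2$edge.length), 1)

  # ultrametric 3-taxon: the closest pair gets the short cherry branches
  D3 <- matrix(c(0, 0.2, 1, 0.2, 0, 1, 1, 1, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  tip_edges <- which(t3$edge[, 2] <= 3L)
  bl <- setNames(t3$edge.length[tip_edges], t3$tip.label[t3$edge[tip_edges, 2]])
  # closed form: v_x = (d_xy + d_xz - d_yz) / 2
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.1, 0.1, 0.9),
               tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("NJ recovers random additive topologies exactly", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- sample(5:8, 1)
    true <- ape::rtree(n, rooted = FALSE)
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_identical(robinson_foulds(est, true), 0L)
  }
})

test_that("Robinson-Foulds counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(robinson_foulds(t1, t1), 0L)
  # each unrooted 4-leaf tree has exactly one non-trivial split; the two
  # splits AB|CD and AC|BD differ -> symmetric difference 2
  expect_identical(robinson_foulds(t1, t2), 2L)
  expect_identical(robinson_foulds(t2, t1), robinson_foulds(t1, t2))
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(t1, t3), "leaf sets")
})

test_that("Newick output round-trips topology and branch lengths", {
  set.seed(62)
  tree <- ape::rtree(7, rooted = FALSE)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_identical(robinson_foulds(tree, back), 0L)
  o <- match(back$tip.label, tree$tip.label)
  cop1 <- ape::cophenetic.phylo(tree)
  cop2 <- ape::cophenetic.phylo(back)[tree$tip.label, tree$tip.label]
  expect_equal(cop2, cop1, tolerance = 1e-9)
})

test_that("logo information content follows the entropy formula", {
  # fully conserved column, no correction: log2(20) bits
  logo <- build_logo(rep("M", 10), correct_small_sample = FALSE)
  expect_equal(logo$ic, log2(20), tolerance = 1e-10)
  # uniform column over all 20 residues: 0 bits
  logo_u <- build_logo(aa_alphabet(), correct_small_sample = FALSE)
  expect_equal(logo_u$ic, 0, tolerance = 1e-10)
  # small-sample correction subtracts 19 / (2 ln2 n)
  logo_c <- build_logo(rep("M", 10), correct_small_sample = TRUE)
  expect_equal(logo_c$ic, log2(20) - 19 / (2 * log(2) * 10),
               tolerance = 1e-10)
  # frequencies normalize and IC respects [0, log2 20] on random input
  set.seed(63)
  strs <- vapply(1:30, function(i) {
    paste(sample(c(aa_alphabet(), "-"), 17, replace = TRUE), collapse = "")
  }, "")
  lg <- build_logo(strs)
  sums <- rowSums(lg$freq)
  expect_true(all(abs(sums[lg$n > 0] - 1) < 1e-9))
  expect_true(all(lg$ic >= 0 & lg$ic <= log2(20)))
  expect_error(build_logo(character()), "at least one")
})
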