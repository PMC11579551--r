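# Evolutionary distances and Neighbor-Joining trees: observed mismatch
# proportions over shared (mutually non-gap) columns, the 20-state protein
# Jukes-Cantor correction d = -(19/20) ln(1 - 20p/19), Saitou-Nei NJ, and
# Robinson-Foulds topology comparison.

#' Observed mismatch proportion between two MSA rows
#'
#' Fraction of differing residues over the columns where both rows are
#' non-gap.
#'
#' @param msa A [star_msa()].
#' @param i,j Row indices or names.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(msa, i, j) {
  stopifnot(inherits(msa, "star_msa"))
  a <- strsplit(msa$rows[[i]], "", fixed = TRUE)[[1]]
  b <- strsplit(msa$rows[[j]], "", fixed = TRUE)[[1]]
  shared <- a != "-" & b != "-"
  if (!any(shared)) {
    stop("rows share no mutually non-gap column")
  }
  mean(a[shared] != b[shared])
}

#' Jukes-Cantor distance for proteins
#'
#' The 20-state generalization of the Jukes-Cantor correction:
#' `d = -(19/20) * ln(1 - (20/19) * p)`. Saturated inputs
#' (`p >= 19/20`) return `cap`.
#'
#' @param p Observed mismatch proportion(s) in `[0, 1]`.
#' @param cap Distance assigned at saturation (default 10).
#' @return Corrected distance(s), same length as `p`.
#' @export
#' @examples
#' jc_distance(0.5)  # ~0.70985
jc_distance <- function(p, cap = 10) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  b <- 19 / 20
  out <- ifelse(p >= b, cap, -b * log(1 - p / b))
  pmin(out, cap)
}

#' Jukes-Cantor distance matrix of a star MSA
#'
#' @param msa A [star_msa()].
#' @param cap Saturation cap passed to [jc_distance()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row
#'   names.
#' @export
dist_jc <- function(msa, cap = 10) {
  n <- length(msa$rows)
  D <- matrix(0, n, n, dimnames = list(msa$names, msa$names))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- jc_distance(p_distance(msa, i, j), cap = cap)
      }
    }
  }
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei Neighbor-Joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero. Two taxa yield the single-edge tree with the distance
#' split evenly.
#'
#' @param D Symmetric numeric matrix with zero diagonal and dimnames, or a
#'   `dist` object.
#' @return An unrooted `phylo` tree (\pkg{ape}).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    half <- D[1L, 2L] / 2
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(D)[1L], half,
                   rownames(D)[2L], half)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Robinson-Foulds distance between trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference). Zero means identical topologies.
#' Used to quantify how similar the KS-domain tree is to the MT-domain
#' tree.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Nonnegative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Write / read Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick I/O (branch lengths kept, no
#' internal node labels written).
#'
#' @param tree A `phylo`.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  tree$node.label <- NULL
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
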