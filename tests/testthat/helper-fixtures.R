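# shared test helpers: toy references, an independent affine
# Needleman-Wunsch score oracle, and small constructors

# a small reference with 3 annotated pocket positions (offset 101)
toy_reference <- function() {
  seq <- "MKALVNDTEWQRSFYHGIPLCVTSANDE"
  # positions 5 (V), 12 (S), 20 (L) in local coordinates
  reference_domain(
    "toy", seq, 101L,
    data.frame(cits_position = c(105L, 113L, 120L),
               reference_residue = c("V", "S", "L"),
               role = c("pocket", "pocket", "pocket"))
  )
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# independent global affine-gap alignment score (gap of length k costs
# open + k * ext); exhaustive dynamic programming over three states
nw_oracle_score <- function(a, b, open = 10, ext = 1, mat = blosum62()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                      Iy[i - 1, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                      Ix[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# substitute a fingerprint string at 1-based slot k
fp_sub <- function(fp, k, aa) {
  ch <- strsplit(fp, "")[[1]]
  ch[k] <- aa
  paste(ch, collapse = "")
}

# four-group synthetic catalog definition shared by miner/pipeline tests;
# group fingerprints keep nonpolar residues at the CitS-2094 slot (slot 11)
# and are pairwise >= 4 substitutions apart, so at divergence 0.05 the
# inter-group distance exceeds twice the intra-group spread
four_group_spec <- function() {
  list(
    list(name = "grpA", pattern = methylation_pattern(3, c(1, 2)),
         count = 3L, fingerprint = "LFVYINTNHEMWVFLWQ"),
    list(name = "grpB", pattern = methylation_pattern(3, 1),
         count = 3L, fingerprint = "IFVWINTNHELWFFLWN"),
    list(name = "grpC", pattern = methylation_pattern(2, 1),
         count = 3L, fingerprint = "LYVYVNTNHEMWLFLFQ"),
    list(name = "grpD", pattern = methylation_pattern(4, c(1, 2, 3)),
         count = 3L, fingerprint = "LFIYIQTNHEVWVFMWE")
  )
}
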