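#include <Rcpp.h>
using namespace Rcpp;

// Best local alignment of a position-specific scoring matrix against a
// protein sequence with affine gap penalties (bits). Smith-Waterman over
// profile columns i = 1..L and sequence positions j = 1..n with three
// states: M (column i matched to residue j), Ix (column skipped), Iy
// (residue skipped). Masked residues (code -1) score -1e9 so an alignment
// cannot match through a previously reported envelope.
//
// Returns the best score with the 1-based sequence/profile spans of the
// best-scoring alignment (the hit envelope).
// [[Rcpp::export(name = ".pssm_local_scan")]]
List pssm_local_scan(NumericMatrix S, IntegerVector seq,
                     double gap_open, double gap_extend) {
  const int L = S.nrow();
  const int n = seq.size();
  const double NEG = -1e12;
  const double MASKED = -1e9;

  std::vector<double> M_prev(n + 1, NEG), Ix_prev(n + 1, NEG),
      Iy_prev(n + 1, NEG);
  std::vector<double> M_cur(n + 1, NEG), Ix_cur(n + 1, NEG),
      Iy_cur(n + 1, NEG);
  // start[j]: sequence index where the local alignment through this cell
  // began (1-based)
  std::vector<int> Ms_prev(n + 1, 0), Ixs_prev(n + 1, 0), Iys_prev(n + 1, 0);
  std::vector<int> Ms_cur(n + 1, 0), Ixs_cur(n + 1, 0), Iys_cur(n + 1, 0);

  double best = 0.0;
  int best_j = 0, best_start = 0, best_i = 0;

  for (int i = 1; i <= L; ++i) {
    M_cur[0] = Ix_cur[0] = Iy_cur[0] = NEG;
    Ms_cur[0] = Ixs_cur[0] = Iys_cur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      const int a = seq[j - 1];
      const double s = (a < 0) ? MASKED : S(i - 1, a);

      // M: extend best of previous diagonal states, or start fresh
      double dM = M_prev[j - 1], dIx = Ix_prev[j - 1], dIy = Iy_prev[j - 1];
      double base = 0.0;
      int src = 0;  // 0 fresh, 1 M, 2 Ix, 3 Iy
      if (dM > base) { base = dM; src = 1; }
      if (dIx > base) { base = dIx; src = 2; }
      if (dIy > base) { base = dIy; src = 3; }
      M_cur[j] = base + s;
      Ms_cur[j] = (src == 0) ? j
                 : (src == 1) ? Ms_prev[j - 1]
                 : (src == 2) ? Ixs_prev[j - 1]
                              : Iys_prev[j - 1];

      // Ix: profile column i unmatched (gap in sequence)
      double openx = M_prev[j] - gap_open;
      double extx = Ix_prev[j] - gap_extend;
      if (openx >= extx) { Ix_cur[j] = openx; Ixs_cur[j] = Ms_prev[j]; }
      else { Ix_cur[j] = extx; Ixs_cur[j] = Ixs_prev[j]; }

      // Iy: sequence residue j unmatched (gap in profile)
      double openy = M_cur[j - 1] - gap_open;
      double exty = Iy_cur[j - 1] - gap_extend;
      if (openy >= exty) { Iy_cur[j] = openy; Iys_cur[j] = Ms_cur[j - 1]; }
      else { Iy_cur[j] = exty; Iys_cur[j] = Iys_cur[j - 1]; }

      if (M_cur[j] > best) {
        best = M_cur[j];
        best_j = j;
        best_start = Ms_cur[j];
        best_i = i;
      }
    }
    std::swap(M_prev, M_cur);
    std::swap(Ix_prev, Ix_cur);
    std::swap(Iy_prev, Iy_cur);
    std::swap(Ms_prev, Ms_cur);
    std::swap(Ixs_prev, Ixs_cur);
    std::swap(Iys_prev, Iys_cur);
  }

  return List::create(_["score"] = best,
                      _["seq_start"] = best_start,
                      _["seq_end"] = best_j,
                      _["profile_end"] = best_i);
}
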