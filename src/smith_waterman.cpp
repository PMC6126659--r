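#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) over pre-encoded residue indices.
// A gap of length k costs gap_open + (k - 1) * gap_extend.
// Tie-breaking: traceback starts at the highest-scoring cell, first in
// row-major order; at each step diagonal is preferred over up (gap in B)
// over left (gap in A), and closing a gap is preferred over extending it.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, NumericMatrix subst,
              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + subst(a[i - 1], b[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(E(i, j), F(i, j))));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> pa, pb;
  if (best > 0.0) {
    int i = bi, j = bj;
    int state = 0;  // 0 = H, 1 = E (left), 2 = F (up)
    while (i > 0 && j > 0) {
      if (state == 0) {
        double h = H(i, j);
        if (h == 0.0) break;
        double diag = H(i - 1, j - 1) + subst(a[i - 1], b[j - 1]);
        if (h == diag) {
          pa.push_back(i); pb.push_back(j);
          --i; --j;
        } else if (h == F(i, j)) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 2) {          // gap in B, consume a_i
        if (F(i, j) == H(i - 1, j) - gap_open) state = 0;  // close gap
        --i;
      } else {                          // gap in A, consume b_j
        if (E(i, j) == H(i, j - 1) - gap_open) state = 0;
        --j;
      }
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best,
                      _["index_a"] = wrap(pa), _["index_b"] = wrap(pb));
}
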