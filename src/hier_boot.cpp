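#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// uniform index in [0, n); uses R's RNG so results follow set.seed()
static inline int draw_index(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

//' Resampled group grand means for the hierarchical bootstrap
//'
//' One group of a nested dataset is a list of batches, each batch a list of
//' numeric sweep vectors (one per cell). For each iteration, batches are drawn
//' with replacement (as many as the group has), within each drawn batch its
//' cells are drawn with replacement (that batch's own cell count), and within
//' each drawn cell its sweeps are drawn with replacement (that cell's own
//' sweep count) unless \code{resample_sweeps} is FALSE (single-sweep designs).
//' The grand mean is either the pooled mean over all drawn sweep values or the
//' mean of drawn-cell means.
//'
//' @noRd
// [[Rcpp::export]]
NumericVector hb_group_means(List batches, int n_iter, bool resample_sweeps,
                             bool cell_means) {
  const int nb = batches.size();
  std::vector< std::vector<NumericVector> > tree(nb);
  for (int b = 0; b < nb; ++b) {
    List cells = batches[b];
    const int nc = cells.size();
    tree[b].reserve(nc);
    for (int c = 0; c < nc; ++c) tree[b].push_back(as<NumericVector>(cells[c]));
  }
  NumericVector out(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    double sum = 0.0, cnt = 0.0;
    for (int bi = 0; bi < nb; ++bi) {
      const int b = draw_index(nb);
      const int nc = (int)tree[b].size();
      for (int ci = 0; ci < nc; ++ci) {
        const int c = draw_index(nc);
        const NumericVector &v = tree[b][c];
        const int ns = v.size();
        double csum = 0.0;
        if (resample_sweeps) {
          for (int si = 0; si < ns; ++si) csum += v[draw_index(ns)];
        } else {
          for (int si = 0; si < ns; ++si) csum += v[si];
        }
        if (cell_means) { sum += csum / ns; cnt += 1.0; }
        else           { sum += csum;      cnt += ns;  }
      }
    }
    out[it] = sum / cnt;
  }
  return out;
}
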