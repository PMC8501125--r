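#include <Rcpp.h>
using namespace Rcpp;

// Sequential acceptance gate evaluated for a whole block of threshold
// combinations at once. Features must be time-ordered; seg_id is the 0-based
// protocol-segment index of each peak (-1 when outside every segment).
// combos columns: theta_II, theta_III, theta_IV, theta_V_max, theta_V_min.
// Returns an ncombo x n_seg matrix of accepted-step counts.
// [[Rcpp::export]]
IntegerMatrix gate_count_grid_cpp(NumericVector peak_t, NumericVector amp,
                                  NumericVector slope, NumericVector area,
                                  IntegerVector seg_id, int n_seg,
                                  NumericMatrix combos) {
  const int n = peak_t.size();
  const int nc = combos.nrow();
  IntegerMatrix counts(nc, n_seg);
  for (int c = 0; c < nc; ++c) {
    const double th2 = combos(c, 0), th3 = combos(c, 1), th4 = combos(c, 2);
    const double tvmax = combos(c, 3), tvmin = combos(c, 4);
    double last = 0.0;
    bool has_last = false;
    for (int i = 0; i < n; ++i) {
      if (amp[i] < th2 || slope[i] < th3 || area[i] < th4) continue;
      if (has_last) {
        // same 1 ns boundary slack as the R gate
        const double gap = peak_t[i] - last;
        if (gap < tvmin - 1e-9 || gap > tvmax + 1e-9) continue;
      }
      has_last = true;
      last = peak_t[i];
      if (seg_id[i] >= 0) counts(c, seg_id[i])++;
    }
  }
  return counts;
}
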