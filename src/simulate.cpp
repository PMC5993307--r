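#include <Rcpp.h>
using namespace Rcpp;

// Embedded-jump-chain simulation with geometric dwell times.
//
// cumjump: 10 x 10 column-wise cumulative jump probabilities (column =
// current state i, rows accumulate over candidate next states f).
// dwell_means: 10 x 10 mean dwell (frames) spent in state i given the
// next state is f (row f, column i); all >= 1.
// Returns n_frames labels for one voxel.  Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".simulate_chain_voxel")]]
IntegerVector simulate_chain_voxel(const int n_frames,
                                   const NumericMatrix& cumjump,
                                   const NumericMatrix& dwell_means,
                                   const int start_state) {
  IntegerVector out(n_frames);
  int state = start_state;
  int t = 0;
  while (t < n_frames) {
    // choose the next state first: dwell may depend on the (f, i) pair
    const double u = unif_rand();
    int nxt = 0;
    while (nxt < 9 && u > cumjump(nxt, state - 1)) ++nxt;
    const double m = dwell_means(nxt, state - 1);
    const int dwell = 1 + (int) R::rgeom(1.0 / m);
    for (int s = 0; s < dwell && t < n_frames; ++s) out[t++] = state;
    state = nxt + 1;
  }
  return out;
}
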