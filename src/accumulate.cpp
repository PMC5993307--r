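#include <Rcpp.h>
using namespace Rcpp;

// Variable-dwell-time transition scan over a voxel x time label matrix.
//
// Per voxel, starting at the first defined frame t: the lag n grows while
// s(v, t + n) == s(v, t); at the first frame with a different label the
// (final, initial, n) cell of the count accumulator is incremented, the
// component accumulators receive X(v, t + n) - X(v, t), the pre/post sums
// receive X(v, t) and X(v, t + n), and t moves to t + n.  A run that
// reaches the end of the series contributes nothing.  Undefined labels
// (0) terminate the current run without a count; scanning resumes at the
// next defined frame.
//
// labels: n_voxels x n_frames integer matrix in 0..10.
// comps: list of voxel x time numeric matrices (may be empty).
// n_max: number of lag layers to allocate (grown by the caller via
//        max_counted_dwell before the call, so no counted dwell exceeds it).
// [[Rcpp::export(name = ".scan_transitions")]]
List scan_transitions(const IntegerMatrix& labels, const List& comps,
                      const int n_max) {
  const int nv = labels.nrow(), nt = labels.ncol();
  const int nc = comps.size();
  IntegerVector a_tc(Dimension(10, 10, n_max));
  std::vector<NumericVector> a_x;
  std::vector<const double*> xp;
  for (int c = 0; c < nc; ++c) {
    a_x.push_back(NumericVector(Dimension(10, 10, n_max)));
    xp.push_back(REAL(comps[c]));
  }
  NumericMatrix pre_sum(10, 10 * nc), post_sum(10, 10 * nc);

  for (int v = 0; v < nv; ++v) {
    int t = 0;
    while (t < nt && labels(v, t) == 0) ++t;
    while (t < nt) {
      const int i = labels(v, t);
      int u = t + 1;
      while (u < nt && labels(v, u) == i) ++u;
      if (u >= nt) break;
      const int f = labels(v, u);
      if (f == 0) {            // undefined sample: drop the run, resume after
        t = u;
        while (t < nt && labels(v, t) == 0) ++t;
        continue;
      }
      const int n = u - t;     // dwell in frames
      if (n > n_max) stop("internal error: dwell exceeds allocated lag depth");
      a_tc[(f - 1) + 10 * (i - 1) + 100 * (n - 1)] += 1;
      for (int c = 0; c < nc; ++c) {
        const double x_pre = xp[c][v + (R_xlen_t)nv * t];
        const double x_post = xp[c][v + (R_xlen_t)nv * u];
        a_x[c][(f - 1) + 10 * (i - 1) + 100 * (n - 1)] += x_post - x_pre;
        pre_sum(f - 1, (i - 1) + 10 * c) += x_pre;
        post_sum(f - 1, (i - 1) + 10 * c) += x_post;
      }
      t = u;                   // post-transition frame becomes the new pre
    }
  }
  List ax(nc);
  for (int c = 0; c < nc; ++c) ax[c] = a_x[c];
  return List::create(_["a_tc"] = a_tc, _["a_x"] = ax,
                      _["pre_sum"] = pre_sum, _["post_sum"] = post_sum);
}

// Longest dwell that would actually be counted (i.e. runs followed by a
// defined, different label), so the caller can size the lag dimension.
// [[Rcpp::export(name = ".max_counted_dwell")]]
int max_counted_dwell(const IntegerMatrix& labels) {
  const int nv = labels.nrow(), nt = labels.ncol();
  int best = 0;
  for (int v = 0; v < nv; ++v) {
    int t = 0;
    while (t < nt && labels(v, t) == 0) ++t;
    while (t < nt) {
      const int i = labels(v, t);
      int u = t + 1;
      while (u < nt && labels(v, u) == i) ++u;
      if (u >= nt) break;
      if (labels(v, u) == 0) {
        t = u;
        while (t < nt && labels(v, t) == 0) ++t;
        continue;
      }
      if (u - t > best) best = u - t;
      t = u;
    }
  }
  return best;
}
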