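#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler integration of Holling type II community dynamics for
// all samples of a dataset at once:
//   dM_i/dt = M_i ( r_i (1 - c_i M_i)
//                   + sum_{j != i} b_ij a_ij M_j / (1 + a_ij TH_ij M_j) )
// M, R and C are nOtus x nSamples; the interaction terms are shared
// across samples and given as a directed edge list (from = j, to = i).
// A sample whose abundances exceed maxAbund is frozen and flagged.
// [[Rcpp::export]]
List hollingEuler(NumericMatrix M0, NumericMatrix R, NumericMatrix C,
                  IntegerVector from, IntegerVector to,
                  NumericVector b, NumericVector a, NumericVector th,
                  double dt, int nSteps, double maxAbund) {
  const int p = M0.nrow(), n = M0.ncol(), ne = from.size();
  NumericMatrix M(clone(M0));
  LogicalVector diverged(n, false);
  std::vector<double> H(p);

  for (int s = 0; s < n; ++s) {
    for (int step = 0; step < nSteps; ++step) {
      std::fill(H.begin(), H.end(), 0.0);
      for (int e = 0; e < ne; ++e) {
        const double m = M(from[e] - 1, s);
        H[to[e] - 1] += b[e] * a[e] * m / (1.0 + a[e] * th[e] * m);
      }
      bool bad = false;
      for (int i = 0; i < p; ++i) {
        double mi = M(i, s);
        mi += dt * mi * (R(i, s) * (1.0 - C(i, s) * mi) + H[i]);
        if (mi < 0.0) mi = 0.0;
        if (mi > maxAbund || !std::isfinite(mi)) { bad = true; }
        M(i, s) = mi;
      }
      if (bad) { diverged[s] = true; break; }
    }
    if ((s & 7) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["M"] = M, _["diverged"] = diverged);
}
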