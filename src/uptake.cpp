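#include <Rcpp.h>
using namespace Rcpp;

// Fractional uptake for a finite cylinder: Mt/Minf = 1 - Sr * Sz where
//   Sr = sum_n (4/alpha_n^2) exp(-alpha_n^2 * Fo_r),  Fo_r = D t / R^2
//   Sz = sum_n 8/((2n+1)^2 pi^2) exp(-(2n+1)^2 pi^2 * Fo_z),  Fo_z = D t / L^2
// (product of the infinite-cylinder and plane-sheet remainders).
// Terms are positive and strictly decreasing in n, so truncation below
// tail_tol is safe.

static double radial_remainder(double fo, const std::vector<double>& alpha2,
                               double tail_tol) {
  double s = 0.0;
  for (size_t n = 0; n < alpha2.size(); ++n) {
    double term = 4.0 / alpha2[n] * std::exp(-alpha2[n] * fo);
    s += term;
    if (term < tail_tol) break;
  }
  return s;
}

static double axial_remainder(double fo, int n_terms, double tail_tol) {
  const double pi2 = M_PI * M_PI;
  double s = 0.0;
  for (int n = 0; n < n_terms; ++n) {
    double k2 = (2.0 * n + 1.0) * (2.0 * n + 1.0);
    double term = 8.0 / (k2 * pi2) * std::exp(-k2 * pi2 * fo);
    s += term;
    if (term < tail_tol) break;
  }
  return s;
}

// Weighted uptake fraction of a population of cylinders (classes with
// length L, radius R, weight w) at times t for diffusivity D. Returns
// sum_i w_i * f_i(t) with each class fraction clipped to [0, 1]; the
// number of clipping events is attached as attribute "n_clipped".
// [[Rcpp::export]]
NumericVector cpp_population_uptake_fraction(NumericVector t, double D,
                                             NumericVector L, NumericVector R,
                                             NumericVector w,
                                             NumericVector alpha, int n_terms,
                                             double tail_tol) {
  int nt = t.size(), nc = L.size();
  std::vector<double> alpha2(alpha.size());
  for (int i = 0; i < alpha.size(); ++i) alpha2[i] = alpha[i] * alpha[i];
  std::vector<double> R2(nc), L2(nc);
  for (int i = 0; i < nc; ++i) { R2[i] = R[i] * R[i]; L2[i] = L[i] * L[i]; }
  NumericVector out(nt);
  int n_clipped = 0;
  for (int j = 0; j < nt; ++j) {
    double tv = t[j];
    if (tv <= 0.0) { out[j] = 0.0; continue; }
    double acc = 0.0;
    for (int i = 0; i < nc; ++i) {
      double Sr = radial_remainder(D * tv / R2[i], alpha2, tail_tol);
      double Sz = axial_remainder(D * tv / L2[i], n_terms, tail_tol);
      double f = 1.0 - Sr * Sz;
      if (f < 0.0) { f = 0.0; ++n_clipped; }
      else if (f > 1.0) { f = 1.0; ++n_clipped; }
      acc += w[i] * f;
    }
    out[j] = acc;
  }
  out.attr("n_clipped") = n_clipped;
  return out;
}
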