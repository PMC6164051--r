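#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Axisymmetric finite-difference solution of the normalized sorption problem
//   du/dFo = (1/rho) du/drho + d2u/drho2 + d2u/dzeta2
// on rho in [0,1], zeta in [0, aspect/2] (symmetry at rho = 0 and zeta = 0,
// Dirichlet u = 1 at rho = 1 and zeta = aspect/2), u(0) = 0, where
// Fo = D t / R^2, rho = r / R, zeta = z / R, aspect = L / R.
// Peaceman-Rachford ADI (Crank-Nicolson in time) with a few damped
// backward-Euler startup steps to suppress ringing from the discontinuous
// initial/boundary data; geometric time-step growth resolves the early
// boundary layer. Uptake is the trapezoid volume average of u.

static void thomas(const std::vector<double>& lo, const std::vector<double>& di,
                   const std::vector<double>& up, std::vector<double>& rhs,
                   std::vector<double>& cp, std::vector<double>& dp) {
  int n = (int)rhs.size();
  cp[0] = up[0] / di[0];
  dp[0] = rhs[0] / di[0];
  for (int i = 1; i < n; ++i) {
    double m = di[i] - lo[i] * cp[i - 1];
    cp[i] = up[i] / m;
    dp[i] = (rhs[i] - lo[i] * dp[i - 1]) / m;
  }
  rhs[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) rhs[i] = dp[i] - cp[i] * rhs[i + 1];
}

// [[Rcpp::export]]
NumericVector cpp_fd_uptake(NumericVector fo, double aspect, int nr, int nz,
                            double dt0, double growth, double dt_max,
                            int n_startup) {
  const int Ni = nr + 1, Nj = nz + 1;       // node counts incl. boundaries
  const double dr = 1.0 / nr;
  const double h = aspect / 2.0;
  const double dz = h / nz;
  const double dr2 = dr * dr, dz2 = dz * dz;

  // radial operator coefficients for unknowns i = 0..nr-1
  std::vector<double> ar(nr), br(nr), cr(nr);
  ar[0] = 0.0; br[0] = -4.0 / dr2; cr[0] = 4.0 / dr2;
  for (int i = 1; i < nr; ++i) {
    double rho = i * dr;
    ar[i] = 1.0 / dr2 - 1.0 / (2.0 * rho * dr);
    br[i] = -2.0 / dr2;
    cr[i] = 1.0 / dr2 + 1.0 / (2.0 * rho * dr);
  }
  // axial operator coefficients for unknowns j = 0..nz-1
  std::vector<double> az(nz), bz(nz), cz(nz);
  az[0] = 0.0; bz[0] = -2.0 / dz2; cz[0] = 2.0 / dz2;
  for (int j = 1; j < nz; ++j) {
    az[j] = 1.0 / dz2; bz[j] = -2.0 / dz2; cz[j] = 1.0 / dz2;
  }

  std::vector<double> u((size_t)Ni * Nj, 0.0);
  for (int j = 0; j < Nj; ++j) u[nr + (size_t)j * Ni] = 1.0;   // rho = 1
  for (int i = 0; i < Ni; ++i) u[i + (size_t)nz * Ni] = 1.0;   // zeta = h

  // trapezoid quadrature weights (rho-weighted volume average)
  std::vector<double> wr(Ni), wz(Nj);
  double swr = 0.0, swz = 0.0;
  for (int i = 0; i < Ni; ++i) {
    wr[i] = (i * dr) * dr * ((i == 0 || i == nr) ? 0.5 : 1.0);
    swr += wr[i];
  }
  for (int j = 0; j < Nj; ++j) {
    wz[j] = dz * ((j == 0 || j == nz) ? 0.5 : 1.0);
    swz += wz[j];
  }
  const double vol = swr * swz;

  std::vector<double> ustar((size_t)Ni * Nj, 0.0);
  for (int j = 0; j < Nj; ++j) ustar[nr + (size_t)j * Ni] = 1.0;
  for (int i = 0; i < Ni; ++i) ustar[i + (size_t)nz * Ni] = 1.0;

  int nmax = std::max(nr, nz);
  std::vector<double> rhs(nmax), cp(nmax), dp(nmax), lo(nmax), di(nmax), up(nmax);

  NumericVector out(fo.size());
  int next = 0;
  while (next < fo.size() && fo[next] <= 0.0) { out[next] = 0.0; ++next; }

  double t = 0.0, dt = dt0;
  long step = 0;
  while (next < fo.size()) {
    if (step > 0) dt = std::min(dt * growth, dt_max);
    bool record = false;
    if (t + dt >= fo[next] - 1e-300) { dt = fo[next] - t; record = true; }
    double theta = (step < n_startup) ? 1.0 : 0.5;
    double mu_im = theta * dt;              // implicit weight per half step
    double mu_ex = (1.0 - theta) * dt;      // explicit weight per half step

    // half step 1: implicit radial, explicit axial
    for (int j = 0; j < nz; ++j) {
      const size_t off = (size_t)j * Ni;
      for (int i = 0; i < nr; ++i) {
        double uij = u[i + off];
        double um = (j == 0) ? u[i + Ni] : u[i + off - Ni]; // symmetry ghost
        double up1 = u[i + off + Ni];
        double Az = az[j] * um + bz[j] * uij + cz[j] * up1;
        if (j == 0) Az = bz[0] * uij + cz[0] * u[i + Ni];
        rhs[i] = uij + mu_ex * Az;
        lo[i] = -mu_im * ar[i];
        di[i] = 1.0 - mu_im * br[i];
        up[i] = -mu_im * cr[i];
      }
      rhs[nr - 1] += mu_im * cr[nr - 1] * 1.0;  // Dirichlet at rho = 1
      std::vector<double> rv(rhs.begin(), rhs.begin() + nr);
      std::vector<double> lv(lo.begin(), lo.begin() + nr);
      std::vector<double> dv(di.begin(), di.begin() + nr);
      std::vector<double> uv(up.begin(), up.begin() + nr);
      thomas(lv, dv, uv, rv, cp, dp);
      for (int i = 0; i < nr; ++i) ustar[i + off] = rv[i];
    }

    // half step 2: implicit axial, explicit radial
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nz; ++j) {
        const size_t off = (size_t)j * Ni;
        double uij = ustar[i + off];
        double Ar;
        if (i == 0) Ar = br[0] * uij + cr[0] * ustar[1 + off];
        else {
          double uright = (i == nr - 1) ? 1.0 : ustar[i + 1 + off];
          Ar = ar[i] * ustar[i - 1 + off] + br[i] * uij + cr[i] * uright;
        }
        rhs[j] = uij + mu_ex * Ar;
        lo[j] = -mu_im * az[j];
        di[j] = 1.0 - mu_im * bz[j];
        up[j] = -mu_im * cz[j];
      }
      rhs[nz - 1] += mu_im * cz[nz - 1] * 1.0;  // Dirichlet at zeta = h
      std::vector<double> rv(rhs.begin(), rhs.begin() + nz);
      std::vector<double> lv(lo.begin(), lo.begin() + nz);
      std::vector<double> dv(di.begin(), di.begin() + nz);
      std::vector<double> uv(up.begin(), up.begin() + nz);
      thomas(lv, dv, uv, rv, cp, dp);
      for (int j = 0; j < nz; ++j) u[i + (size_t)j * Ni] = rv[j];
    }

    t += dt;
    ++step;
    if (record) {
      double s = 0.0;
      for (int j = 0; j < Nj; ++j) {
        const size_t off = (size_t)j * Ni;
        double srow = 0.0;
        for (int i = 0; i < Ni; ++i) srow += u[i + off] * wr[i];
        s += srow * wz[j];
      }
      out[next] = s / vol;
      ++next;
    }
    if (step > 5000000L) stop("time stepping failed to reach requested times");
  }
  return out;
}
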