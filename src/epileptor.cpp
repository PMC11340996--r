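#include <Rcpp.h>
using namespace Rcpp;

// Stochastic Heun integration of the 2D-reduced Epileptor on a network.
//
//   x_i' = I1 - x_i^3 - 2 x_i^2 - z_i
//   z_i' = (1/tau0) * ( 4 (x_i - x0_i) - z_i
//            + coupling_sign * K * sum_j C[i,j] (x_j - x_i) )
//
// Additive Gaussian noise (sd = noise_sd, per sqrt(dt)) enters both state
// variables.  The noise increments are pre-generated in R (noise_x/noise_z,
// n_regions x n_steps) so that each region's stream depends only on the seed
// and the region index: with K = 0 a region's trajectory is then identical
// to the corresponding single-region run.
//
// Returns a list with x and z as (n_regions x (n_steps + 1)) matrices, or
// diverged = true if |x| exceeded 1e3.  Raw-pointer arithmetic throughout:
// this routine sits inside the MAP objective and is called thousands of
// times per inversion.
// [[Rcpp::export(name = ".epileptor_heun")]]
List epileptor_heun(NumericVector x0, double tau0, double K, double I1,
                    NumericMatrix C, NumericVector x_init,
                    NumericVector z_init, double dt, int n_steps,
                    double noise_sd, NumericMatrix noise_x,
                    NumericMatrix noise_z, double coupling_sign) {
  const int L = x0.size();
  NumericMatrix x(L, n_steps + 1), z(L, n_steps + 1);
  double *xm = REAL(x), *zm = REAL(z);
  const double *x0p = REAL(x0), *Cp = REAL(C);
  const double *nxp = REAL(noise_x), *nzp = REAL(noise_z);
  const bool noisy = noise_sd > 0.0;

  std::vector<double> xc(L), zc(L), dx1(L), dz1(L), xp(L), zp(L), wx(L), wz(L);
  for (int i = 0; i < L; ++i) {
    xc[i] = x_init[i]; zc[i] = z_init[i];
    xm[i] = xc[i]; zm[i] = zc[i];
  }

  const double sqdt = std::sqrt(dt), inv_tau = 1.0 / tau0;
  bool diverged = false;
  int div_step = -1;

  for (int t = 0; t < n_steps && !diverged; ++t) {
    for (int i = 0; i < L; ++i) {
      double coup = 0.0;
      if (K != 0.0) {
        const double *ci = Cp + i;   // row i, column-major stride L
        for (int j = 0; j < L; ++j) coup += ci[(size_t)j * L] * (xc[j] - xc[i]);
      }
      const double xi = xc[i];
      dx1[i] = I1 - xi * xi * xi - 2.0 * xi * xi - zc[i];
      dz1[i] = (4.0 * (xi - x0p[i]) - zc[i] + coupling_sign * K * coup) * inv_tau;
      if (noisy) {
        wx[i] = noise_sd * sqdt * nxp[i + (size_t)t * L];
        wz[i] = noise_sd * sqdt * nzp[i + (size_t)t * L];
      } else { wx[i] = 0.0; wz[i] = 0.0; }
      xp[i] = xc[i] + dt * dx1[i] + wx[i];
      zp[i] = zc[i] + dt * dz1[i] + wz[i];
    }
    double *xcol = xm + (size_t)(t + 1) * L, *zcol = zm + (size_t)(t + 1) * L;
    for (int i = 0; i < L; ++i) {
      double coup = 0.0;
      if (K != 0.0) {
        const double *ci = Cp + i;
        for (int j = 0; j < L; ++j) coup += ci[(size_t)j * L] * (xp[j] - xp[i]);
      }
      const double xi = xp[i];
      const double dx2 = I1 - xi * xi * xi - 2.0 * xi * xi - zp[i];
      const double dz2 = (4.0 * (xi - x0p[i]) - zp[i]
                          + coupling_sign * K * coup) * inv_tau;
      xc[i] += 0.5 * dt * (dx1[i] + dx2) + wx[i];
      zc[i] += 0.5 * dt * (dz1[i] + dz2) + wz[i];
      if (std::fabs(xc[i]) > 1e3) { diverged = true; div_step = t + 1; }
      xcol[i] = xc[i]; zcol[i] = zc[i];
    }
  }

  return List::create(_["x"] = x, _["z"] = z,
                      _["diverged"] = diverged, _["div_step"] = div_step);
}
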