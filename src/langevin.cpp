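#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Brownian dynamics) integrator on a uniform grid.
// drift and sigma (= sqrt(2 D)) are precomputed on the grid and linearly
// interpolated; boundaries are reflecting.  Uses R's RNG so that set.seed()
// in the calling R code makes runs reproducible.
// [[Rcpp::export]]
NumericVector langevin_path_cpp(double z0, int n_steps, double dt,
                                double zmin, double dz,
                                NumericVector drift, NumericVector sigma,
                                double lo, double hi) {
  int ng = drift.size();
  NumericVector z(n_steps + 1);
  z[0] = z0;
  double cur = z0;
  double sqdt = std::sqrt(dt);
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    double x = (cur - zmin) / dz;
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i > ng - 2) i = ng - 2;
    double f = x - i;
    double a = drift[i] * (1.0 - f) + drift[i + 1] * f;
    double s = sigma[i] * (1.0 - f) + sigma[i + 1] * f;
    double nz = cur + a * dt + s * sqdt * norm_rand();
    int guard = 0;
    while ((nz < lo || nz > hi) && guard++ < 64) {
      if (nz < lo) nz = 2.0 * lo - nz; else nz = 2.0 * hi - nz;
    }
    if (nz < lo) nz = lo;
    if (nz > hi) nz = hi;
    cur = nz;
    z[t + 1] = cur;
  }
  return z;
}
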