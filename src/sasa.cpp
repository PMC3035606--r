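#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible-area kernel.
//
// coords: n x 3 atom centres; radii: n expanded radii (vdW + probe);
// points: m x 3 unit-sphere test directions (deterministic lattice, so the
// result is bit-reproducible for a fixed point set).
// Returns per-atom accessible area = (exposed points / m) * 4*pi*r^2.
// [[Rcpp::export(name = ".sasaKernel")]]
NumericVector sasaKernel(NumericMatrix coords, NumericVector radii,
                         NumericMatrix points) {
  const int n = coords.nrow();
  const int m = points.nrow();
  NumericVector area(n);
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = radii[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double lim = ri + radii[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    if (nb.empty()) {
      exposed = m;
    } else {
      for (int k = 0; k < m; ++k) {
        const double px = xi + ri * points(k, 0);
        const double py = yi + ri * points(k, 1);
        const double pz = zi + ri * points(k, 2);
        bool free_point = true;
        for (size_t q = 0; q < nb.size(); ++q) {
          const int j = nb[q];
          const double dx = px - coords(j, 0);
          const double dy = py - coords(j, 1);
          const double dz = pz - coords(j, 2);
          const double rj = radii[j];
          if (dx * dx + dy * dy + dz * dz < rj * rj) {
            free_point = false;
            break;
          }
        }
        if (free_point) ++exposed;
      }
    }
    area[i] = (double)exposed / m * 4.0 * M_PI * ri * ri;
  }
  return area;
}

// Worst steric overlap (r_i + r_j - d) of each probe atom against a fixed
// environment. probe: p x 3, env: n x 3, radii likewise. Returns the overall
// maximum overlap across all pairs (can be negative when nothing touches).
// [[Rcpp::export(name = ".worstOverlap")]]
double worstOverlap(NumericMatrix probe, NumericVector probeRadii,
                    NumericMatrix env, NumericVector envRadii) {
  double worst = R_NegInf;
  for (int i = 0; i < probe.nrow(); ++i) {
    const double xi = probe(i, 0), yi = probe(i, 1), zi = probe(i, 2);
    for (int j = 0; j < env.nrow(); ++j) {
      const double dx = env(j, 0) - xi;
      const double dy = env(j, 1) - yi;
      const double dz = env(j, 2) - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ov = probeRadii[i] + envRadii[j] - d;
      if (ov > worst) worst = ov;
    }
  }
  return worst;
}
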