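#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area.
//
// xyz: n x 3 atom coordinates (Angstrom); radii: per-atom vdW radii;
// probe: solvent probe radius; pts: m x 3 unit-sphere test points
// (deterministic golden-spiral set generated on the R side).
//
// For each atom, test points are scaled onto its solvent-expanded sphere of
// radius r_i + probe; a point is accessible if it lies outside every
// neighbour's solvent-expanded sphere. SASA_i = 4*pi*(r_i+p)^2 * accessible/m.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, NumericMatrix pts) {
  const int n = xyz.nrow();
  const int m = pts.nrow();
  if (radii.size() != n) stop("radii must match atom count");

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = xyz(i, 0); Y[i] = xyz(i, 1); Z[i] = xyz(i, 2);
  }

  NumericVector out(n);
  std::vector<int> nb;
  nb.reserve(64);

  for (int i = 0; i < n; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i], ri = R[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - X[j], dy = yi - Y[j], dz = zi - Z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double cut = ri + R[j];
      if (d2 < cut * cut) {
        if (d2 < 1e-6) stop("degenerate_geometry: coincident atoms");
        nb.push_back(j);
      }
    }
    int acc = 0;
    const int nnb = (int) nb.size();
    for (int p = 0; p < m; ++p) {
      const double px = xi + ri * pts(p, 0);
      const double py = yi + ri * pts(p, 1);
      const double pz = zi + ri * pts(p, 2);
      bool free_pt = true;
      for (int k = 0; k < nnb; ++k) {
        const int j = nb[k];
        const double dx = px - X[j], dy = py - Y[j], dz = pz - Z[j];
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double) acc / (double) m);
  }
  return out;
}
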