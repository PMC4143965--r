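#include <Rcpp.h>
using namespace Rcpp;

// Translation edge-corrected 3D Ripley K on an axis-aligned box window.
// Each unordered pair is binned at the first grid value >= its distance so
// that K(d) uses the closed inequality ||x_k - x_l|| <= d; both ordered
// pairs contribute, weighted by the inverse set covariance of the box.
// Normalisation is vol(B)^2 / N^2.
// [[Rcpp::export]]
NumericVector cpp_k3_translation(const NumericMatrix& xyz,
                                 const NumericVector& sides,
                                 const NumericVector& grid) {
  const int n = xyz.nrow();
  const int ng = grid.size();
  const double sx = sides[0], sy = sides[1], sz = sides[2];
  const double vol = sx * sy * sz;
  const double dmax = grid[ng - 1];
  std::vector<double> bin(ng, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = std::fabs(xi - xyz(j, 0));
      const double dy = std::fabs(yi - xyz(j, 1));
      const double dz = std::fabs(zi - xyz(j, 2));
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > dmax) continue;
      const double gamma = (sx - dx) * (sy - dy) * (sz - dz);
      if (gamma <= 0.0) continue;  // impossible while d < shortest side; guard only
      const int idx = std::lower_bound(grid.begin(), grid.end(), d) - grid.begin();
      bin[idx] += 2.0 / gamma;     // (k,l) and (l,k)
    }
  }
  NumericVector K(ng);
  double acc = 0.0;
  const double scale = vol * vol / (static_cast<double>(n) * static_cast<double>(n));
  for (int g = 0; g < ng; ++g) {
    acc += bin[g];
    K[g] = scale * acc;
  }
  return K;
}

// Random sequential adsorption of hard spheres with lognormal diameters.
// Candidates draw a fresh uniform location and a fresh diameter; a candidate
// is rejected when the centre distance to any accepted sphere is below the
// sum of exclusion radii (radius_factor * diameter each). Uses R's RNG so
// set.seed() makes runs reproducible.
// [[Rcpp::export]]
List cpp_rsa(const NumericVector& sides,
             const NumericVector& origin,
             const int n_target,
             const double mu,
             const double sigma,
             const double radius_factor,
             const int max_consecutive_rejections) {
  std::vector<double> X, Y, Z, D, R;
  X.reserve(n_target); Y.reserve(n_target); Z.reserve(n_target);
  D.reserve(n_target); R.reserve(n_target);
  int consec = 0;
  bool jammed = false;
  while (static_cast<int>(X.size()) < n_target) {
    const double x = origin[0] + unif_rand() * sides[0];
    const double y = origin[1] + unif_rand() * sides[1];
    const double z = origin[2] + unif_rand() * sides[2];
    const double diam = ::Rf_rlnorm(mu, sigma);
    const double r = radius_factor * diam;
    bool ok = true;
    const int m = static_cast<int>(X.size());
    for (int k = 0; k < m; ++k) {
      const double dx = x - X[k];
      const double dy = y - Y[k];
      const double dz = z - Z[k];
      const double lim = r + R[k];
      if (dx * dx + dy * dy + dz * dz < lim * lim) { ok = false; break; }
    }
    if (ok) {
      X.push_back(x); Y.push_back(y); Z.push_back(z);
      D.push_back(diam); R.push_back(r);
      consec = 0;
    } else if (++consec >= max_consecutive_rejections) {
      jammed = true;
      break;
    }
  }
  return List::create(_["x"] = wrap(X), _["y"] = wrap(Y), _["z"] = wrap(Z),
                      _["feret"] = wrap(D), _["jammed"] = jammed);
}

// Exhaustive nearest-neighbour distances (no edge correction).
// [[Rcpp::export]]
NumericVector cpp_nn_distances(const NumericMatrix& xyz) {
  const int n = xyz.nrow();
  NumericVector nn(n, R_PosInf);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < nn[i]) nn[i] = d;
      if (d < nn[j]) nn[j] = d;
    }
  }
  return nn;
}
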