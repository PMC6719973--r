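// Shrake-Rupley solvent-accessible surface area on a deterministic
// golden-spiral point set. Used for the lipophilic-contact and
// buried-polar-surface terms of the binding score.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       IntegerVector query, double probe, int n_points) {
  const int n = xyz.nrow();
  const int nq = query.size();
  NumericVector area(nq);

  // golden-spiral unit sphere points (deterministic)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = zk;
  }

  std::vector<int> nb;
  nb.reserve(64);
  for (int qi = 0; qi < nq; ++qi) {
    const int i = query[qi] - 1;  // 1-based from R
    const double Ri = radii[i] + probe;
    // neighbour prefilter
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double Rj = radii[j] + probe;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = Ri + Rj;
      if (d2 < rr * rr) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = xyz(i, 0) + Ri * px[k];
      double sy = xyz(i, 1) + Ri * py[k];
      double sz = xyz(i, 2) + Ri * pz[k];
      bool occl = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double Rj = radii[j] + probe;
        double dx = sx - xyz(j, 0);
        double dy = sy - xyz(j, 1);
        double dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { occl = true; break; }
      }
      if (!occl) ++exposed;
    }
    area[qi] = 4.0 * M_PI * Ri * Ri * exposed / n_points;
  }
  return area;
}

// Minimum distance from each row of `a` to any row of `b`.
// [[Rcpp::export(name = ".min_dist_cpp")]]
NumericVector min_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
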