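// d-dimensional convex hull volume by incremental insertion (beneath-beyond).
//
// Points are joggled by a tiny deterministic perturbation before insertion so
// that degenerate configurations (coplanar facet fans, repeated points) fall
// into general position; the volume error this introduces is of the order of
// joggle * surface area, far below the tolerances used anywhere in the
// package. Truly degenerate inputs (affine rank < d) are detected on the R
// side and never reach this code with the expectation of a positive volume.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// fixed-seed xorshift generator for the joggle: independent of R's RNG so
// hull volumes do not perturb or depend on the caller's random stream
inline double joggle_unif(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return (s >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
}

// determinant of an m x m matrix (row-major), Gaussian elimination with
// partial pivoting; destroys its input
double det_inplace(std::vector<double> &a, int m) {
  double det = 1.0;
  for (int c = 0; c < m; ++c) {
    int piv = c;
    double best = std::fabs(a[c * m + c]);
    for (int r = c + 1; r < m; ++r) {
      double v = std::fabs(a[r * m + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return 0.0;
    if (piv != c) {
      for (int j = 0; j < m; ++j) std::swap(a[c * m + j], a[piv * m + j]);
      det = -det;
    }
    det *= a[c * m + c];
    double inv = 1.0 / a[c * m + c];
    for (int r = c + 1; r < m; ++r) {
      double f = a[r * m + c] * inv;
      if (f == 0.0) continue;
      for (int j = c; j < m; ++j) a[r * m + j] -= f * a[c * m + j];
    }
  }
  return det;
}

struct Facet {
  std::vector<int> v;        // d vertex indices, ascending
  std::vector<double> nrm;   // unit outward normal
  double off;                // nrm . x = off on the facet plane
  bool alive;
};

// outward-oriented facet from d point indices; returns false if the points
// are (numerically) affinely dependent
bool make_facet(const std::vector<double> &P, int d, std::vector<int> verts,
                const std::vector<double> &interior, Facet &out) {
  std::sort(verts.begin(), verts.end());
  const double *q0 = &P[(size_t)verts[0] * d];
  // edges: (d-1) x d
  std::vector<double> E((size_t)(d - 1) * d);
  for (int i = 1; i < d; ++i) {
    const double *qi = &P[(size_t)verts[i] * d];
    for (int j = 0; j < d; ++j) E[(size_t)(i - 1) * d + j] = qi[j] - q0[j];
  }
  // generalized cross product via cofactors
  std::vector<double> nrm(d);
  std::vector<double> minor((size_t)(d - 1) * (d - 1));
  double norm2 = 0.0;
  for (int j = 0; j < d; ++j) {
    for (int r = 0; r < d - 1; ++r) {
      int cc = 0;
      for (int c = 0; c < d; ++c) {
        if (c == j) continue;
        minor[(size_t)r * (d - 1) + cc++] = E[(size_t)r * d + c];
      }
    }
    double m = det_inplace(minor, d - 1);
    nrm[j] = ((j % 2) == 0) ? m : -m;
    norm2 += nrm[j] * nrm[j];
  }
  double norm = std::sqrt(norm2);
  if (norm == 0.0 || !R_FINITE(norm)) return false;
  double off = 0.0, side = 0.0;
  for (int j = 0; j < d; ++j) {
    nrm[j] /= norm;
    off += nrm[j] * q0[j];
    side += nrm[j] * interior[j];
  }
  if (side > off) {  // flip so the interior point is beneath the facet
    for (int j = 0; j < d; ++j) nrm[j] = -nrm[j];
    off = -off;
  }
  out.v = std::move(verts);
  out.nrm = std::move(nrm);
  out.off = off;
  out.alive = true;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".quickhull_cpp")]]
List quickhull_cpp(NumericMatrix pts, double joggle) {
  const int n = pts.nrow(), d = pts.ncol();
  if (n < d + 1) stop("need at least d+1 points");
  if (d < 2) stop("dimension must be >= 2");

  // copy column-major R matrix to row-major, find coordinate scale
  std::vector<double> P((size_t)n * d);
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) {
      double v = pts(i, j);
      P[(size_t)i * d + j] = v;
      if (std::fabs(v) > scale) scale = std::fabs(v);
    }
  if (scale == 0.0) scale = 1.0;
  uint64_t jstate = 0x9E3779B97F4A7C15ULL;
  if (joggle > 0.0) {
    double amp = joggle * scale;
    for (size_t k = 0; k < P.size(); ++k)
      P[k] += (joggle_unif(jstate) - 0.5) * 2.0 * amp;
  }
  const double tol = 1e-12 * scale * d;

  // --- initial simplex: farthest-point Gram-Schmidt ---------------------
  std::vector<int> simp;
  {
    int a = 0, b = 0;
    double best = -1.0;
    for (int i = 0; i < n; ++i) {  // farthest pair seeds (approx: from point 0)
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double e = P[(size_t)i * d + j] - P[j];
        s += e * e;
      }
      if (s > best) { best = s; b = i; }
    }
    simp.push_back(a == b ? 0 : a);
    if (b != simp[0]) simp.push_back(b);
    std::vector<double> basis;  // orthonormal rows spanning current affine set
    while ((int)simp.size() < d + 1) {
      // extend basis with the newest direction
      if (simp.size() >= 2 && (int)basis.size() / d < (int)simp.size() - 1) {
        std::vector<double> e(d);
        for (int j = 0; j < d; ++j)
          e[j] = P[(size_t)simp.back() * d + j] - P[(size_t)simp[0] * d + j];
        int nb = basis.size() / d;
        for (int r = 0; r < nb; ++r) {
          double dot = 0.0;
          for (int j = 0; j < d; ++j) dot += e[j] * basis[(size_t)r * d + j];
          for (int j = 0; j < d; ++j) e[j] -= dot * basis[(size_t)r * d + j];
        }
        double nrm = 0.0;
        for (int j = 0; j < d; ++j) nrm += e[j] * e[j];
        nrm = std::sqrt(nrm);
        if (nrm > 0) for (int j = 0; j < d; ++j) basis.push_back(e[j] / nrm);
      }
      // farthest point from the current affine subspace
      int nb = basis.size() / d;
      int pick = -1;
      double bestr = tol;
      std::vector<double> e(d);
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < d; ++j)
          e[j] = P[(size_t)i * d + j] - P[(size_t)simp[0] * d + j];
        for (int r = 0; r < nb; ++r) {
          double dot = 0.0;
          for (int j = 0; j < d; ++j) dot += e[j] * basis[(size_t)r * d + j];
          for (int j = 0; j < d; ++j) e[j] -= dot * basis[(size_t)r * d + j];
        }
        double res = 0.0;
        for (int j = 0; j < d; ++j) res += e[j] * e[j];
        res = std::sqrt(res);
        if (res > bestr) { bestr = res; pick = i; }
      }
      if (pick < 0)
        return List::create(_["volume"] = 0.0,
                            _["vertices"] = IntegerVector(0),
                            _["degenerate"] = true);
      simp.push_back(pick);
    }
  }

  std::vector<double> interior(d, 0.0);
  for (int k = 0; k <= d; ++k)
    for (int j = 0; j < d; ++j)
      interior[j] += P[(size_t)simp[k] * d + j] / (d + 1);

  std::vector<Facet> facets;
  facets.reserve(64);
  for (int omit = 0; omit <= d; ++omit) {
    std::vector<int> verts;
    for (int k = 0; k <= d; ++k) if (k != omit) verts.push_back(simp[k]);
    Facet f;
    if (!make_facet(P, d, verts, interior, f))
      return List::create(_["volume"] = 0.0, _["vertices"] = IntegerVector(0),
                          _["degenerate"] = true);
    facets.push_back(std::move(f));
  }

  // --- incremental insertion -------------------------------------------
  std::vector<bool> in_simplex(n, false);
  for (int k = 0; k <= d; ++k) in_simplex[simp[k]] = true;

  for (int i = 0; i < n; ++i) {
    if (in_simplex[i]) continue;
    const double *p = &P[(size_t)i * d];
    std::vector<int> visible;
    for (int f = 0; f < (int)facets.size(); ++f) {
      if (!facets[f].alive) continue;
      double s = -facets[f].off;
      for (int j = 0; j < d; ++j) s += facets[f].nrm[j] * p[j];
      if (s > tol) visible.push_back(f);
    }
    if (visible.empty()) continue;  // beneath every facet: interior point
    // horizon ridges: (d-1)-subsets seen by exactly one visible facet
    std::map<std::vector<int>, int> ridge_count;
    for (int f : visible) {
      const std::vector<int> &v = facets[f].v;
      for (int omit = 0; omit < d; ++omit) {
        std::vector<int> ridge;
        ridge.reserve(d - 1);
        for (int k = 0; k < d; ++k) if (k != omit) ridge.push_back(v[k]);
        ++ridge_count[ridge];
      }
    }
    std::vector<Facet> fresh;
    for (const auto &rc : ridge_count) {
      if (rc.second != 1) continue;
      std::vector<int> verts = rc.first;
      verts.push_back(i);
      Facet f;
      if (make_facet(P, d, verts, interior, f)) fresh.push_back(std::move(f));
    }
    if (fresh.empty()) continue;  // numerically flush with the hull: skip
    for (int f : visible) facets[f].alive = false;
    for (auto &f : fresh) facets.push_back(std::move(f));
    // compact occasionally
    if (facets.size() > 256) {
      size_t dead = 0;
      for (const auto &f : facets) if (!f.alive) ++dead;
      if (dead > facets.size() / 2) {
        std::vector<Facet> kept;
        kept.reserve(facets.size() - dead);
        for (auto &f : facets) if (f.alive) kept.push_back(std::move(f));
        facets.swap(kept);
      }
    }
  }

  // --- volume: fan of simplices from the interior point -----------------
  double dfact = 1.0;
  for (int j = 2; j <= d; ++j) dfact *= j;
  double vol = 0.0;
  std::vector<double> M((size_t)d * d);
  std::vector<bool> on_hull(n, false);
  int nfacets = 0;
  for (const auto &f : facets) {
    if (!f.alive) continue;
    ++nfacets;
    for (int k = 0; k < d; ++k) {
      on_hull[f.v[k]] = true;
      const double *q = &P[(size_t)f.v[k] * d];
      for (int j = 0; j < d; ++j) M[(size_t)k * d + j] = q[j] - interior[j];
    }
    vol += std::fabs(det_inplace(M, d)) / dfact;
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (on_hull[i]) verts.push_back(i + 1);
  return List::create(_["volume"] = vol,
                      _["vertices"] = wrap(verts),
                      _["degenerate"] = false,
                      _["n_facets"] = nfacets);
}
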