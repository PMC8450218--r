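// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralization.
// Backs the alpha-complex boundary volume; callers are expected to pass
// coordinates scaled to O(1) with a small deterministic jitter so that
// cospherical degeneracies (regular grids of digitized points) are broken.

#include <Rcpp.h>
#include <map>
#include <array>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Tet {
  int v[4];
  double c[3];   // circumcenter
  double r2;     // squared circumradius
  bool alive;
};

// Circumcenter of 4 points via the linear system 2(b-a).x = |b|^2-|a|^2 etc.
// Returns false when the tetrahedron is (nearly) flat; r2 is then set huge so
// the sliver is absorbed at large alpha without affecting volumes.
static bool circumsphere(const double *p0, const double *p1,
                         const double *p2, const double *p3,
                         double *c, double &r2) {
  double A[3][3], b[3];
  const double *ps[3] = {p1, p2, p3};
  for (int i = 0; i < 3; ++i) {
    double nb = 0.0, na = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (ps[i][j] - p0[j]);
      nb += ps[i][j] * ps[i][j];
      na += p0[j] * p0[j];
    }
    b[i] = nb - na;
  }
  double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-14) {
    c[0] = c[1] = c[2] = 0.0;
    r2 = 1e30;
    return false;
  }
  double inv[3][3];
  inv[0][0] =  (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  inv[0][1] = -(A[0][1] * A[2][2] - A[0][2] * A[2][1]) / det;
  inv[0][2] =  (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  inv[1][0] = -(A[1][0] * A[2][2] - A[1][2] * A[2][0]) / det;
  inv[1][1] =  (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  inv[1][2] = -(A[0][0] * A[1][2] - A[0][2] * A[1][0]) / det;
  inv[2][0] =  (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  inv[2][1] = -(A[0][0] * A[2][1] - A[0][1] * A[2][0]) / det;
  inv[2][2] =  (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  for (int i = 0; i < 3; ++i)
    c[i] = inv[i][0] * b[0] + inv[i][1] * b[1] + inv[i][2] * b[2];
  double d0 = c[0] - p0[0], d1 = c[1] - p0[1], d2 = c[2] - p0[2];
  r2 = d0 * d0 + d1 * d1 + d2 * d2;
  return true;
}

static double tet_volume(const double *a, const double *b,
                         const double *c, const double *d) {
  double u[3], v[3], w[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = b[i] - a[i];
    v[i] = c[i] - a[i];
    w[i] = d[i] - a[i];
  }
  double det = u[0] * (v[1] * w[2] - v[2] * w[1]) -
               u[1] * (v[0] * w[2] - v[2] * w[0]) +
               u[2] * (v[0] * w[1] - v[1] * w[0]);
  return std::fabs(det) / 6.0;
}

// [[Rcpp::export]]
List delaunay_tets_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  // coordinates, super-tetra appended
  std::vector<std::array<double, 3>> P(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      P[i][j] = pts(i, j);
      if (P[i][j] < lo[j]) lo[j] = P[i][j];
      if (P[i][j] > hi[j]) hi[j] = P[i][j];
    }
  double ctr[3], span = 0.0;
  for (int j = 0; j < 3; ++j) {
    ctr[j] = 0.5 * (lo[j] + hi[j]);
    span = std::max(span, hi[j] - lo[j]);
  }
  double R = 50.0 * (span > 0 ? span : 1.0);
  // big regular tetrahedron around the cloud
  double sv[4][3] = {{ 1,  1,  1}, { 1, -1, -1}, {-1,  1, -1}, {-1, -1,  1}};
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j)
      P[n + k][j] = ctr[j] + R * sv[k][j];

  std::vector<Tet> tets;
  tets.reserve(8 * n);
  {
    Tet t;
    t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2; t.v[3] = n + 3;
    circumsphere(P[t.v[0]].data(), P[t.v[1]].data(),
                 P[t.v[2]].data(), P[t.v[3]].data(), t.c, t.r2);
    t.alive = true;
    tets.push_back(t);
  }

  typedef std::array<int, 3> Face;
  std::vector<int> bad;
  std::map<Face, std::pair<int, int>> faceCount; // face -> (count, opposite vert unused)

  for (int ip = 0; ip < n; ++ip) {
    const double *p = P[ip].data();
    bad.clear();
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double d0 = p[0] - tets[t].c[0];
      double d1 = p[1] - tets[t].c[1];
      double d2 = p[2] - tets[t].c[2];
      if (d0 * d0 + d1 * d1 + d2 * d2 < tets[t].r2)
        bad.push_back(t);
    }
    faceCount.clear();
    for (int bi : bad) {
      const int *v = tets[bi].v;
      for (int k = 0; k < 4; ++k) {
        Face f = {v[(k + 1) % 4], v[(k + 2) % 4], v[(k + 3) % 4]};
        if (f[0] > f[1]) std::swap(f[0], f[1]);
        if (f[1] > f[2]) std::swap(f[1], f[2]);
        if (f[0] > f[1]) std::swap(f[0], f[1]);
        faceCount[f].first++;
      }
      tets[bi].alive = false;
    }
    for (std::map<Face, std::pair<int, int>>::const_iterator it = faceCount.begin();
         it != faceCount.end(); ++it) {
      if (it->second.first != 1) continue; // interior cavity face
      Tet t;
      t.v[0] = it->first[0];
      t.v[1] = it->first[1];
      t.v[2] = it->first[2];
      t.v[3] = ip;
      circumsphere(P[t.v[0]].data(), P[t.v[1]].data(),
                   P[t.v[2]].data(), P[t.v[3]].data(), t.c, t.r2);
      t.alive = true;
      tets.push_back(t);
    }
    if (ip % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // keep live tets with no super-tetra vertex
  std::vector<int> keep;
  for (int t = 0; t < (int)tets.size(); ++t) {
    if (!tets[t].alive) continue;
    const int *v = tets[t].v;
    if (v[0] >= n || v[1] >= n || v[2] >= n || v[3] >= n) continue;
    keep.push_back(t);
  }
  const int m = (int)keep.size();
  IntegerMatrix out(m, 4);
  NumericVector rad(m), vol(m);
  for (int i = 0; i < m; ++i) {
    const Tet &t = tets[keep[i]];
    for (int k = 0; k < 4; ++k) out(i, k) = t.v[k] + 1; // 1-based
    rad[i] = std::sqrt(t.r2);
    vol[i] = tet_volume(P[t.v[0]].data(), P[t.v[1]].data(),
                        P[t.v[2]].data(), P[t.v[3]].data());
  }
  return List::create(_["tets"] = out, _["circumradius"] = rad,
                      _["volume"] = vol);
}
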