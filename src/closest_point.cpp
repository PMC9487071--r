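#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; Voronoi-region walk.
// Writes the closest point into out[3].
static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid {
  double lo[3];
  double h[3];
  int dims[3];
  std::vector<std::vector<int> > cells;

  int cell_index(int ix, int iy, int iz) const {
    return (iz * dims[1] + iy) * dims[0] + ix;
  }
  int clampi(double x, int axis) const {
    int i = (int)std::floor((x - lo[axis]) / h[axis]);
    if (i < 0) i = 0;
    if (i >= dims[axis]) i = dims[axis] - 1;
    return i;
  }
};

static void build_grid(const NumericMatrix &V, const IntegerMatrix &F,
                       TriGrid &g) {
  const int nv = V.nrow(), nf = F.nrow();
  double hi[3];
  for (int a = 0; a < 3; ++a) { g.lo[a] = V(0, a); hi[a] = V(0, a); }
  for (int i = 1; i < nv; ++i)
    for (int a = 0; a < 3; ++a) {
      if (V(i, a) < g.lo[a]) g.lo[a] = V(i, a);
      if (V(i, a) > hi[a]) hi[a] = V(i, a);
    }
  // target roughly one triangle per cell, capped to keep memory bounded
  double target = std::cbrt((double)std::max(nf, 1));
  for (int a = 0; a < 3; ++a) {
    double ext = hi[a] - g.lo[a];
    if (ext <= 0) ext = 1e-9;
    int d = (int)std::ceil(target);
    if (d < 1) d = 1;
    if (d > 64) d = 64;
    g.dims[a] = d;
    g.h[a] = ext / d * (1.0 + 1e-12) + 1e-300;
  }
  g.cells.assign((size_t)g.dims[0] * g.dims[1] * g.dims[2],
                 std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    double tlo[3], thi[3];
    for (int a = 0; a < 3; ++a) {
      double v0 = V(F(f, 0), a), v1 = V(F(f, 1), a), v2 = V(F(f, 2), a);
      tlo[a] = std::min(v0, std::min(v1, v2));
      thi[a] = std::max(v0, std::max(v1, v2));
    }
    int i0 = g.clampi(tlo[0], 0), i1 = g.clampi(thi[0], 0);
    int j0 = g.clampi(tlo[1], 1), j1 = g.clampi(thi[1], 1);
    int k0 = g.clampi(tlo[2], 2), k1 = g.clampi(thi[2], 2);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.cells[g.cell_index(i, j, k)].push_back(f);
  }
}

// squared distance from point to the axis-aligned box of cell (i,j,k)
static inline double cell_dist2(const TriGrid &g, const double *q, int i,
                                int j, int k) {
  double d2 = 0.0;
  int idx[3] = {i, j, k};
  for (int a = 0; a < 3; ++a) {
    double clo = g.lo[a] + idx[a] * g.h[a];
    double chi = clo + g.h[a];
    double d = 0.0;
    if (q[a] < clo) d = clo - q[a];
    else if (q[a] > chi) d = q[a] - chi;
    d2 += d * d;
  }
  return d2;
}

// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  if (nf == 0) stop("reference mesh has no faces");
  TriGrid g;
  build_grid(V, F, g);

  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  IntegerVector tri(nq);
  std::vector<int> stamp((size_t)nf, -1);
  int maxdim = std::max(g.dims[0], std::max(g.dims[1], g.dims[2]));

  for (int qi = 0; qi < nq; ++qi) {
    double q[3] = {Q(qi, 0), Q(qi, 1), Q(qi, 2)};
    int ci = g.clampi(q[0], 0), cj = g.clampi(q[1], 1), ck = g.clampi(q[2], 2);
    double best2 = R_PosInf, bestp[3] = {0, 0, 0};
    int besttri = -1;

    for (int r = 0; r <= maxdim; ++r) {
      // lower bound on distance to any cell outside the (2r-1)-cube around home
      if (besttri >= 0 && r > 0) {
        double blo = R_PosInf;
        bool inside = true;
        for (int a = 0; a < 3; ++a) {
          int idx = (a == 0) ? ci : (a == 1 ? cj : ck);
          double clo = g.lo[a] + (idx - (r - 1)) * g.h[a];
          double chi = g.lo[a] + (idx + r) * g.h[a];
          if (q[a] < clo || q[a] > chi) { inside = false; break; }
          blo = std::min(blo, std::min(q[a] - clo, chi - q[a]));
        }
        if (inside && blo * blo > best2) break;
      }
      int i0 = std::max(ci - r, 0), i1 = std::min(ci + r, g.dims[0] - 1);
      int j0 = std::max(cj - r, 0), j1 = std::min(cj + r, g.dims[1] - 1);
      int k0 = std::max(ck - r, 0), k1 = std::min(ck + r, g.dims[2] - 1);
      bool any_cell = false;
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // only the shell at Chebyshev radius r
            if (std::max(std::abs(i - ci),
                         std::max(std::abs(j - cj), std::abs(k - ck))) != r)
              continue;
            any_cell = true;
            if (besttri >= 0 && cell_dist2(g, q, i, j, k) > best2) continue;
            const std::vector<int> &lst = g.cells[g.cell_index(i, j, k)];
            for (size_t t = 0; t < lst.size(); ++t) {
              int f = lst[t];
              if (stamp[f] == qi) continue;
              stamp[f] = qi;
              double a[3], b[3], c[3], cp[3];
              for (int ax = 0; ax < 3; ++ax) {
                a[ax] = V(F(f, 0), ax);
                b[ax] = V(F(f, 1), ax);
                c[ax] = V(F(f, 2), ax);
              }
              closest_pt_triangle(q, a, b, c, cp);
              double d2 = 0;
              for (int ax = 0; ax < 3; ++ax) {
                double d = q[ax] - cp[ax];
                d2 += d * d;
              }
              // tie on distance -> keep lowest triangle index (determinism)
              if (d2 < best2 || (d2 == best2 && f < besttri)) {
                best2 = d2;
                besttri = f;
                for (int ax = 0; ax < 3; ++ax) bestp[ax] = cp[ax];
              }
            }
          }
      if (!any_cell && besttri >= 0) break;
    }
    pts(qi, 0) = bestp[0]; pts(qi, 1) = bestp[1]; pts(qi, 2) = bestp[2];
    dist[qi] = std::sqrt(best2);
    tri[qi] = besttri; // 0-based; R wrapper shifts
  }
  return List::create(Named("point") = pts, Named("dist") = dist,
                      Named("tri") = tri);
}
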