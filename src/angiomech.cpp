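// Compiled kernels: hyperelastic growth stress and FE assembly, exact 3D
// Euclidean distance transform, weighted graph distances, and spatial
// neighbour searches for the vascular network.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- small dense 3x3 helpers (row-major double[9]) -------------------------

static inline double det3(const double* m) {
  return m[0] * (m[4] * m[8] - m[5] * m[7])
       - m[1] * (m[3] * m[8] - m[5] * m[6])
       + m[2] * (m[3] * m[7] - m[4] * m[6]);
}

static inline void inv3(const double* m, double* out) {
  double d = det3(m);
  double id = 1.0 / d;
  out[0] =  (m[4] * m[8] - m[5] * m[7]) * id;
  out[1] = -(m[1] * m[8] - m[2] * m[7]) * id;
  out[2] =  (m[1] * m[5] - m[2] * m[4]) * id;
  out[3] = -(m[3] * m[8] - m[5] * m[6]) * id;
  out[4] =  (m[0] * m[8] - m[2] * m[6]) * id;
  out[5] = -(m[0] * m[5] - m[2] * m[3]) * id;
  out[6] =  (m[3] * m[7] - m[4] * m[6]) * id;
  out[7] = -(m[0] * m[7] - m[1] * m[6]) * id;
  out[8] =  (m[0] * m[4] - m[1] * m[3]) * id;
}

static inline void mul3(const double* a, const double* b, double* out) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out[3 * i + j] = a[3 * i] * b[j] + a[3 * i + 1] * b[3 + j] + a[3 * i + 2] * b[6 + j];
}

static inline void mulT3(const double* a, const double* b, double* out) {
  // a^T * b
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out[3 * i + j] = a[i] * b[j] + a[3 + i] * b[3 + j] + a[6 + i] * b[6 + j];
}

static inline void mul3T(const double* a, const double* b, double* out) {
  // a * b^T
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out[3 * i + j] = a[3 * i] * b[3 * j] + a[3 * i + 1] * b[3 * j + 1] + a[3 * i + 2] * b[3 * j + 2];
}

// ---- constitutive law ------------------------------------------------------
// Generalised polynomial stored energy on the elastic part, isochoric terms
// scaled by the ECM integrity factor zeta, volumetric term unscaled:
//   W = zeta*[c10(I1b-3)+c20(I1b-3)^2+c01(I2b-3)+c02(I2b-3)^2
//             +c11(I1b-3)(I2b-3)] + kappa (J-1)^2/2
// Second Piola-Kirchhoff w.r.t. the intermediate (grown) configuration:
//   S_e = 2 dW/dC_e.
// pars = c10, c20, c01, c02, c11, kappa.
static void pk2_intermediate(const double* Ce, double zeta, const double* pars,
                             double* Se) {
  const double c10 = pars[0], c20 = pars[1], c01 = pars[2],
               c02 = pars[3], c11 = pars[4], kappa = pars[5];
  double I1 = Ce[0] + Ce[4] + Ce[8];
  double CC[9];
  mul3(Ce, Ce, CC);
  double trCC = CC[0] + CC[4] + CC[8];
  double I2 = 0.5 * (I1 * I1 - trCC);
  double J2 = det3(Ce);
  double J = std::sqrt(J2);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double Jm43 = Jm23 * Jm23;
  double I1b = Jm23 * I1, I2b = Jm43 * I2;
  double Ci[9];
  inv3(Ce, Ci);
  double W1 = zeta * (c10 + 2.0 * c20 * (I1b - 3.0) + c11 * (I2b - 3.0));
  double W2 = zeta * (c01 + 2.0 * c02 * (I2b - 3.0) + c11 * (I1b - 3.0));
  double vol = kappa * (J - 1.0) * J;
  for (int i = 0; i < 9; ++i) {
    double eye = (i == 0 || i == 4 || i == 8) ? 1.0 : 0.0;
    Se[i] = 2.0 * W1 * Jm23 * (eye - (I1 / 3.0) * Ci[i])
          + 2.0 * W2 * (Jm43 * (I1 * eye - Ce[i]) - (2.0 / 3.0) * I2b * Ci[i])
          + vol * Ci[i];
  }
}

// First Piola-Kirchhoff stress w.r.t. the reference configuration with
// multiplicative growth: P = F * (Jg Fg^-1 S_e Fg^-T).
// Fginv/Jg precomputed by caller; returns false on det(F_e) <= 0.
static bool pk1_reference(const double* F, const double* Fginv, double Jg,
                          double zeta, const double* pars, double* P) {
  double Fe[9], Ce[9], Se[9], tmp[9], Sx[9];
  mul3(F, Fginv, Fe);
  if (det3(Fe) <= 0.0) return false;
  mulT3(Fe, Fe, Ce);
  pk2_intermediate(Ce, zeta, pars, Se);
  mul3(Fginv, Se, tmp);
  mul3T(tmp, Fginv, Sx);
  for (int i = 0; i < 9; ++i) Sx[i] *= Jg;
  mul3(F, Sx, P);
  return true;
}

// [[Rcpp::export(name = ".cppStressPK2")]]
NumericVector cpp_stress_pk2(NumericVector F, NumericVector Fg, double zeta,
                             NumericVector pars) {
  // Reference second Piola-Kirchhoff (pull-back, incl. Jg) - used for
  // cross-checking against the R constitutive implementation.
  double Fginv[9], Fe[9], Ce[9], Se[9], tmp[9], Sx[9];
  inv3(&Fg[0], Fginv);
  double Jg = det3(&Fg[0]);
  mul3(&F[0], Fginv, Fe);
  mulT3(Fe, Fe, Ce);
  pk2_intermediate(Ce, zeta, &pars[0], Se);
  mul3(Fginv, Se, tmp);
  mul3T(tmp, Fginv, Sx);
  NumericVector out(9);
  for (int i = 0; i < 9; ++i) out[i] = Jg * Sx[i];
  return out;
}

// ---- solid FE assembly -----------------------------------------------------
// gradN: per element, per quadrature point (nq=8), per local node (8),
// gradient of shape function w.r.t. X, flattened [e][q][a][d].
// dofmap: N x 3 integer, 0-based free-dof index or -1 if Dirichlet-fixed.

struct ElemData {
  const double* gradN;  // 8*8*3
  const double* dV;     // 8
  const double* Fginv;  // 8*9
  const double* Jg;     // 8
  const double* zeta;   // 8
  const double* pars;   // 6
};

static bool elem_residual(const ElemData& ed, const double* ue, double* fe) {
  for (int k = 0; k < 24; ++k) fe[k] = 0.0;
  for (int q = 0; q < 8; ++q) {
    const double* gN = ed.gradN + q * 24;
    double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    for (int a = 0; a < 8; ++a) {
      const double* g = gN + 3 * a;
      const double* u = ue + 3 * a;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[3 * i + j] += u[i] * g[j];
    }
    double P[9];
    if (!pk1_reference(F, ed.Fginv + 9 * q, ed.Jg[q], ed.zeta[q], ed.pars, P))
      return false;
    double w = ed.dV[q];
    for (int a = 0; a < 8; ++a) {
      const double* g = gN + 3 * a;
      for (int i = 0; i < 3; ++i)
        fe[3 * a + i] += w * (P[3 * i] * g[0] + P[3 * i + 1] * g[1] + P[3 * i + 2] * g[2]);
    }
  }
  return true;
}

// [[Rcpp::export(name = ".cppSolidAssemble")]]
List cpp_solid_assemble(IntegerMatrix conn, NumericMatrix u,
                        NumericVector gradN, NumericVector dV,
                        NumericVector Fg, NumericVector zeta,
                        IntegerVector matid, NumericMatrix matpars,
                        IntegerMatrix dofmap, bool want_tangent) {
  int E = conn.nrow();
  int N = u.nrow();
  NumericMatrix res(N, 3);
  // precompute Fg inverses
  std::vector<double> Fginv(E * 8 * 9), Jg(E * 8);
  for (int e = 0; e < E; ++e)
    for (int q = 0; q < 8; ++q) {
      const double* g = &Fg[0] + (e * 8 + q) * 9;
      inv3(g, &Fginv[(e * 8 + q) * 9]);
      Jg[e * 8 + q] = det3(g);
    }
  int ntrip = want_tangent ? E * 576 : 0;
  IntegerVector Ti(ntrip), Tj(ntrip);
  NumericVector Tx(ntrip);
  int nt = 0;
  bool ok = true;
  double fe[24], fe2[24], ue[24], ue2[24];
  for (int e = 0; e < E && ok; ++e) {
    ElemData ed;
    ed.gradN = &gradN[0] + e * 192;
    ed.dV = &dV[0] + e * 8;
    ed.Fginv = &Fginv[e * 72];
    ed.Jg = &Jg[e * 8];
    ed.zeta = &zeta[0] + e * 8;
    double pars[6];
    for (int k = 0; k < 6; ++k) pars[k] = matpars(matid[e], k);
    ed.pars = pars;
    double umax = 0.0;
    for (int a = 0; a < 8; ++a) {
      int n = conn(e, a);
      for (int i = 0; i < 3; ++i) {
        ue[3 * a + i] = u(n, i);
        umax = std::max(umax, std::fabs(ue[3 * a + i]));
      }
    }
    if (!elem_residual(ed, ue, fe)) { ok = false; break; }
    for (int a = 0; a < 8; ++a) {
      int n = conn(e, a);
      for (int i = 0; i < 3; ++i) res(n, i) += fe[3 * a + i];
    }
    if (want_tangent) {
      double h = 1e-7 * (1.0 + umax);
      int gdof[24];
      for (int a = 0; a < 8; ++a) {
        int n = conn(e, a);
        for (int i = 0; i < 3; ++i) gdof[3 * a + i] = dofmap(n, i);
      }
      for (int k = 0; k < 24; ++k) {
        if (gdof[k] < 0) continue;  // fixed dof: column not needed
        for (int m = 0; m < 24; ++m) ue2[m] = ue[m];
        ue2[k] += h;
        if (!elem_residual(ed, ue2, fe2)) { ok = false; break; }
        for (int m = 0; m < 24; ++m) {
          if (gdof[m] < 0) continue;
          double v = (fe2[m] - fe[m]) / h;
          if (v != 0.0) {
            Ti[nt] = gdof[m];
            Tj[nt] = gdof[k];
            Tx[nt] = v;
            ++nt;
          }
        }
      }
    }
  }
  if (!ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["res"] = res,
                      _["i"] = head(Ti, nt), _["j"] = head(Tj, nt),
                      _["x"] = head(Tx, nt));
}

// Per-element quadrature-averaged stress measures after a converged solve.
// Returns reference 2nd PK (6 comps, xx yy zz xy xz yz), reference
// hydrostatic -tr(S)/3, Cauchy hydrostatic -tr(sigma)/3, and mean det(F).
// [[Rcpp::export(name = ".cppSolidStressField")]]
List cpp_solid_stress_field(IntegerMatrix conn, NumericMatrix u,
                            NumericVector gradN, NumericVector dV,
                            NumericVector Fg, NumericVector zeta,
                            IntegerVector matid, NumericMatrix matpars) {
  int E = conn.nrow();
  NumericMatrix Sout(E, 6);
  NumericVector thp_ref(E), thp_cau(E), detF(E);
  for (int e = 0; e < E; ++e) {
    double pars[6];
    for (int k = 0; k < 6; ++k) pars[k] = matpars(matid[e], k);
    double ue[24];
    for (int a = 0; a < 8; ++a) {
      int n = conn(e, a);
      for (int i = 0; i < 3; ++i) ue[3 * a + i] = u(n, i);
    }
    double Ssum[9] = {0}, trref = 0, trcau = 0, jsum = 0, vsum = 0;
    for (int q = 0; q < 8; ++q) {
      const double* gN = &gradN[0] + e * 192 + q * 24;
      double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            F[3 * i + j] += ue[3 * a + i] * gN[3 * a + j];
      const double* g = &Fg[0] + (e * 8 + q) * 9;
      double Fginv[9];
      inv3(g, Fginv);
      double Jgq = det3(g);
      double Fe[9], Ce[9], Se[9], tmp[9], Sx[9];
      mul3(F, Fginv, Fe);
      mulT3(Fe, Fe, Ce);
      pk2_intermediate(Ce, zeta[e * 8 + q], pars, Se);
      mul3(Fginv, Se, tmp);
      mul3T(tmp, Fginv, Sx);
      for (int i = 0; i < 9; ++i) Sx[i] *= Jgq;
      double w = dV[e * 8 + q];
      vsum += w;
      for (int i = 0; i < 9; ++i) Ssum[i] += w * Sx[i];
      trref += w * (Sx[0] + Sx[4] + Sx[8]);
      double P[9], sig[9];
      mul3(F, Sx, P);
      mul3T(P, F, sig);  // P F^T = F S F^T
      double Jt = det3(F);
      trcau += w * (sig[0] + sig[4] + sig[8]) / Jt;
      jsum += w * Jt;
    }
    Sout(e, 0) = Ssum[0] / vsum; Sout(e, 1) = Ssum[4] / vsum;
    Sout(e, 2) = Ssum[8] / vsum; Sout(e, 3) = Ssum[1] / vsum;
    Sout(e, 4) = Ssum[2] / vsum; Sout(e, 5) = Ssum[5] / vsum;
    thp_ref[e] = -trref / (3.0 * vsum);
    thp_cau[e] = -trcau / (3.0 * vsum);
    detF[e] = jsum / vsum;
  }
  return List::create(_["S"] = Sout, _["thp_ref"] = thp_ref,
                      _["thp_cauchy"] = thp_cau, _["detF"] = detF);
}

// Accumulate triplet values into the @x slot of a pre-built dgCMatrix given a
// precomputed map triplet -> x-slot position (1-based).
// [[Rcpp::export(name = ".cppAccumulate")]]
NumericVector cpp_accumulate(IntegerVector map, NumericVector vals, int nx) {
  NumericVector out(nx);
  int n = map.size();
  for (int k = 0; k < n; ++k) out[map[k] - 1] += vals[k];
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) --------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// occupancy: 1 where a vessel passes, 0 elsewhere; returns distances in voxel
// units (multiply by voxel size in the caller). A large finite sentinel
// stands in for infinity so that all-empty scan lines stay well defined.
// [[Rcpp::export(name = ".cppEDT3")]]
NumericVector cpp_edt3(LogicalVector occ, int nx, int ny, int nz) {
  static const double BIG = 1e15;
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = occ[i] ? 0.0 : BIG;
  std::vector<double> f(std::max(nx, std::max(ny, nz))),
      d(std::max(nx, std::max(ny, nz)));
  // along x (fastest index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t off = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[off + i];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) g[off + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[off + (size_t)j * nx];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) g[off + (size_t)j * nx] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[off + (size_t)k * nx * ny];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) g[off + (size_t)k * nx * ny] = d[k];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---- multi-source Dijkstra over the segment graph --------------------------
// [[Rcpp::export(name = ".cppGraphDist")]]
NumericVector cpp_graph_dist(int n, IntegerVector a, IntegerVector b,
                             NumericVector w, IntegerVector sources) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  int m = a.size();
  for (int e = 0; e < m; ++e) {
    adj[a[e]].push_back(std::make_pair(b[e], w[e]));
    adj[b[e]].push_back(std::make_pair(a[e], w[e]));
  }
  std::vector<double> dist(n, INF);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    dist[sources[s]] = 0.0;
    pq.push(std::make_pair(0.0, sources[s]));
  }
  while (!pq.empty()) {
    QN top = pq.top();
    pq.pop();
    if (top.first > dist[top.second]) continue;
    int u = top.second;
    for (size_t k = 0; k < adj[u].size(); ++k) {
      int v = adj[u][k].first;
      double nd = top.first + adj[u][k].second;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(std::make_pair(nd, v));
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}

// ---- spatial searches ------------------------------------------------------
// Mean over sample points of the distance to the nearest sample on a
// different vessel; expanding-ring grid search. Returns per-point distances
// (Inf where no foreign vessel exists).
// [[Rcpp::export(name = ".cppForeignNN")]]
NumericVector cpp_foreign_nn(NumericMatrix p, IntegerVector vid, double cell) {
  static const double INF = std::numeric_limits<double>::infinity();
  int np = p.nrow();
  NumericVector out(np, INF);
  if (np == 0) return out;
  double xmin[3], xmax[3];
  for (int d = 0; d < 3; ++d) {
    xmin[d] = xmax[d] = p(0, d);
    for (int i = 1; i < np; ++i) {
      xmin[d] = std::min(xmin[d], p(i, d));
      xmax[d] = std::max(xmax[d], p(i, d));
    }
  }
  int dims[3];
  for (int d = 0; d < 3; ++d)
    dims[d] = std::max(1, (int)std::floor((xmax[d] - xmin[d]) / cell) + 1);
  std::vector<std::vector<int> > buckets((size_t)dims[0] * dims[1] * dims[2]);
  std::vector<int> ci(np), cj(np), ck(np);
  for (int i = 0; i < np; ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)std::floor((p(i, d) - xmin[d]) / cell);
      c[d] = std::min(std::max(c[d], 0), dims[d] - 1);
    }
    ci[i] = c[0]; cj[i] = c[1]; ck[i] = c[2];
    buckets[(size_t)c[2] * dims[0] * dims[1] + (size_t)c[1] * dims[0] + c[0]].push_back(i);
  }
  int maxring = std::max(dims[0], std::max(dims[1], dims[2]));
  for (int iq = 0; iq < np; ++iq) {
    double best = INF;
    for (int ring = 0; ring <= maxring; ++ring) {
      if (best < INF && (double)(ring - 1) * cell > std::sqrt(best)) break;
      bool any = false;
      for (int dz = -ring; dz <= ring; ++dz)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring)
              continue;
            int cx = ci[iq] + dx, cy = cj[iq] + dy, cz = ck[iq] + dz;
            if (cx < 0 || cy < 0 || cz < 0 || cx >= dims[0] || cy >= dims[1] || cz >= dims[2])
              continue;
            any = true;
            const std::vector<int>& bk =
                buckets[(size_t)cz * dims[0] * dims[1] + (size_t)cy * dims[0] + cx];
            for (size_t t = 0; t < bk.size(); ++t) {
              int i = bk[t];
              if (vid[i] == vid[iq]) continue;
              double dd = 0.0;
              for (int d = 0; d < 3; ++d) {
                double dv = p(i, d) - p(iq, d);
                dd += dv * dv;
              }
              if (dd < best) best = dd;
            }
          }
      if (!any && ring > 0 && best < INF) break;
      if (!any && ring > maxring) break;
    }
    out[iq] = std::sqrt(best);
  }
  return out;
}
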