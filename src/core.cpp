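// Explicit quasi-static core for the growing bilayer and the coupled
// axon-bundle agent loop.  Plane strain, 4-node quads, 2x2 Gauss,
// total-Lagrangian assembly around a compressible neo-Hookean law with a
// multiplicative growth decomposition F = Fe.Fg.  Units: mm, day, Pa.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG (splitmix64).  Every agent owns an independent stream
// derived from the run seed, so trajectories are bit-reproducible and
// independent of R's global RNG.
// ---------------------------------------------------------------------------
static inline uint64_t sm64_next(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double sm64_unif(uint64_t& s) {
  return (sm64_next(s) >> 11) * (1.0 / 9007199254740992.0);
}
// one Gaussian per call (Box-Muller, second variate discarded so the stream
// position is a pure function of the draw count)
static inline double sm64_norm(uint64_t& s) {
  double u1 = sm64_unif(s), u2 = sm64_unif(s);
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}
static inline uint64_t mix_seed(uint64_t base, uint64_t idx) {
  uint64_t s = base ^ (0xA5A5A5A5DEADBEEFULL * (idx + 1));
  return sm64_next(s);
}

// [[Rcpp::export]]
double cpp_mix_seed(double base, double idx) {
  uint64_t v = mix_seed((uint64_t)base, (uint64_t)idx);
  return (double)(v % 2147483647ULL);
}

// [[Rcpp::export]]
NumericVector cpp_stream_uniform(double seed, double stream, int n) {
  uint64_t s = mix_seed((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sm64_unif(s);
  return out;
}

// Per-agent stream layout: 3 uniforms (x, y, theta) then one Gaussian per
// agent step.  cpp_seed_bundles and cpp_agent_noise recompute the same
// stream, so R-level sandboxes reproduce run_core draws exactly.
// [[Rcpp::export]]
NumericMatrix cpp_seed_bundles(double seed, int n, double w, double y_band,
                               double theta_mid, double theta_halfwidth) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    uint64_t s = mix_seed((uint64_t)seed, (uint64_t)(i + 1));
    out(i, 0) = sm64_unif(s) * w;
    out(i, 1) = sm64_unif(s) * y_band;
    out(i, 2) = theta_mid + (2.0 * sm64_unif(s) - 1.0) * theta_halfwidth;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_agent_noise(double seed, int agent, int n_steps) {
  uint64_t s = mix_seed((uint64_t)seed, (uint64_t)agent);
  sm64_unif(s); sm64_unif(s); sm64_unif(s);  // skip the 3 seeding draws
  NumericVector out(n_steps);
  for (int i = 0; i < n_steps; ++i) out[i] = sm64_norm(s);
  return out;
}

// ---------------------------------------------------------------------------
// Material point: Cauchy stress and strain energy for region-specific growth
// ---------------------------------------------------------------------------
struct StressOut {
  double T11, T22, T12, T33, W, Je;
};

// growth principal stretches (gx, gy, gz) and det Fg for a region
static inline void growth_diag(int region, double th_ctx, double th_sub,
                               double& gx, double& gy, double& gz, double& dFg) {
  if (region == 1) {  // cortex: tangential area growth, n0 = e_y
    double r = std::sqrt(th_ctx);
    gx = r; gy = 1.0; gz = r; dFg = th_ctx;
  } else {            // ECM and fiber: isotropic volumetric growth
    double r = std::cbrt(th_sub);
    gx = r; gy = r; gz = r; dFg = th_sub;
  }
}

// Jbar <= 0 evaluates the volumetric term at the local Je; Jbar > 0 uses the
// supplied element-averaged elastic Jacobian (mean dilatation / B-bar, which
// avoids volumetric locking of the fully integrated quad near
// incompressibility while keeping the deviatoric term fully integrated)
static inline bool stress_point(double F11, double F12, double F21, double F22,
                                double gx, double gy, double gz,
                                double mu, double k, StressOut& o,
                                double Jbar = -1.0) {
  // Fe = F . Fg^{-1} with diagonal Fg: column scaling; Fe33 = 1/gz
  double e11 = F11 / gx, e12 = F12 / gy;
  double e21 = F21 / gx, e22 = F22 / gy;
  double e33 = 1.0 / gz;
  double det2 = e11 * e22 - e12 * e21;
  double Je = det2 * e33;
  if (!(Je > 0.0)) return false;
  double b11 = e11 * e11 + e12 * e12;
  double b22 = e21 * e21 + e22 * e22;
  double b12 = e11 * e21 + e12 * e22;
  double b33 = e33 * e33;
  double trb = b11 + b22 + b33;
  double Jm23 = std::pow(Je, -2.0 / 3.0);
  double Jm53 = Jm23 / Je;
  double Jv = Jbar > 0.0 ? Jbar : Je;
  double p = k * (Jv - 1.0);
  o.T11 = mu * Jm53 * (b11 - trb / 3.0) + p;
  o.T22 = mu * Jm53 * (b22 - trb / 3.0) + p;
  o.T33 = mu * Jm53 * (b33 - trb / 3.0) + p;
  o.T12 = mu * Jm53 * b12;
  o.W = 0.5 * mu * (Jm23 * trb - 3.0) + 0.5 * k * (Jv - 1.0) * (Jv - 1.0);
  o.Je = Je;
  return true;
}

// elastic Jacobian at a deformation-gradient point (for the element average)
static inline double elastic_J(double F11, double F12, double F21, double F22,
                               double gx, double gy, double gz) {
  return (F11 * F22 - F12 * F21) / (gx * gy * gz);
}

// Exposed single-point kernel so R-level tests can cross-check the solver's
// constitutive path against the pure-R implementation.
// [[Rcpp::export]]
NumericVector cpp_stress_point(NumericMatrix F2, int region, double th_ctx,
                               double th_sub, double mu, double k) {
  double gx, gy, gz, dFg;
  growth_diag(region, th_ctx, th_sub, gx, gy, gz, dFg);
  StressOut o;
  if (!stress_point(F2(0, 0), F2(0, 1), F2(1, 0), F2(1, 1), gx, gy, gz, mu, k, o))
    stop("element inversion: det(Fe) <= 0");
  return NumericVector::create(_["T11"] = o.T11, _["T22"] = o.T22,
                               _["T12"] = o.T12, _["T33"] = o.T33,
                               _["W"] = o.W, _["Je"] = o.Je);
}

// ---------------------------------------------------------------------------
// Structured bilayer grid
// ---------------------------------------------------------------------------
struct Grid {
  int nex, ney, nnx, nny, nel, nnode, cortex_row0;
  double es, w, h, tc;
  std::vector<double> X;           // reference coords, 2*nnode (perturbed)
  std::vector<int> region;         // 0 ecm, 1 cortex, 2 fiber
  std::vector<double> mu;          // per element
  bool perturbed;
  // per-geometry gauss data: dNdX (4 gp x 4 nodes x 2) and detJ0 (4 gp)
  std::vector<double> dNdX;        // ngeo*4*8
  std::vector<double> detJ0;       // ngeo*4
  int node(int i, int j) const { return j * nnx + i; }
  void enodes(int e, int* n) const {
    int i = e % nex, j = e / nex;
    n[0] = node(i, j); n[1] = node(i + 1, j);
    n[2] = node(i + 1, j + 1); n[3] = node(i, j + 1);
  }
  int geo(int e) const { return perturbed ? e : 0; }
};

static const double GP = 0.57735026918962576451;  // 1/sqrt(3)
static const double gpx[4] = {-GP, GP, GP, -GP};
static const double gpe[4] = {-GP, -GP, GP, GP};

static void shape_dxi(double xi, double eta, double* dNdxi, double* dNdeta) {
  dNdxi[0] = -(1 - eta) / 4; dNdxi[1] = (1 - eta) / 4;
  dNdxi[2] = (1 + eta) / 4;  dNdxi[3] = -(1 + eta) / 4;
  dNdeta[0] = -(1 - xi) / 4; dNdeta[1] = -(1 + xi) / 4;
  dNdeta[2] = (1 + xi) / 4;  dNdeta[3] = (1 - xi) / 4;
}
static void shape_N(double xi, double eta, double* N) {
  N[0] = (1 - xi) * (1 - eta) / 4; N[1] = (1 + xi) * (1 - eta) / 4;
  N[2] = (1 + xi) * (1 + eta) / 4; N[3] = (1 - xi) * (1 + eta) / 4;
}

static void grid_build(Grid& g, double w, double h, double tc, double es,
                       double perturb) {
  g.w = w; g.h = h; g.tc = tc; g.es = es;
  g.nex = (int)std::lround(w / es);
  g.ney = (int)std::lround((h + tc) / es);
  g.nnx = g.nex + 1; g.nny = g.ney + 1;
  g.nel = g.nex * g.ney; g.nnode = g.nnx * g.nny;
  g.cortex_row0 = (int)std::lround(h / es);
  g.perturbed = perturb > 0.0;
  g.X.resize(2 * g.nnode);
  double H = h + tc;
  for (int j = 0; j < g.nny; ++j)
    for (int i = 0; i < g.nnx; ++i) {
      double x = i * es, y = j * es;
      if (g.perturbed && j > 0) {
        // deterministic smooth imperfection, zero at the bottom
        double f = y / H;
        double dy = perturb * f *
          (std::sin(3.0 * 2.0 * M_PI * x / w) +
           0.5 * std::sin(7.0 * 2.0 * M_PI * x / w + 1.0));
        y += dy;
      }
      g.X[2 * g.node(i, j)] = x;
      g.X[2 * g.node(i, j) + 1] = y;
    }
  g.region.assign(g.nel, 0);
  for (int e = 0; e < g.nel; ++e)
    if (e / g.nex >= g.cortex_row0) g.region[e] = 1;
  // gauss geometry
  int ngeo = g.perturbed ? g.nel : 1;
  g.dNdX.resize((size_t)ngeo * 32);
  g.detJ0.resize((size_t)ngeo * 4);
  for (int eg = 0; eg < ngeo; ++eg) {
    int n[4];
    double xc[4], yc[4];
    if (g.perturbed) {
      g.enodes(eg, n);
      for (int a = 0; a < 4; ++a) { xc[a] = g.X[2 * n[a]]; yc[a] = g.X[2 * n[a] + 1]; }
    } else {
      xc[0] = 0; xc[1] = es; xc[2] = es; xc[3] = 0;
      yc[0] = 0; yc[1] = 0;  yc[2] = es; yc[3] = es;
    }
    for (int q = 0; q < 4; ++q) {
      double dNdxi[4], dNdeta[4];
      shape_dxi(gpx[q], gpe[q], dNdxi, dNdeta);
      double J11 = 0, J12 = 0, J21 = 0, J22 = 0;
      for (int a = 0; a < 4; ++a) {
        J11 += xc[a] * dNdxi[a];  J12 += yc[a] * dNdxi[a];
        J21 += xc[a] * dNdeta[a]; J22 += yc[a] * dNdeta[a];
      }
      double dJ = J11 * J22 - J12 * J21;
      if (dJ <= 0) stop("non-positive reference Jacobian");
      g.detJ0[(size_t)eg * 4 + q] = dJ;
      double i11 = J22 / dJ, i12 = -J12 / dJ, i21 = -J21 / dJ, i22 = J11 / dJ;
      for (int a = 0; a < 4; ++a) {
        g.dNdX[((size_t)eg * 4 + q) * 8 + 2 * a]     = dNdxi[a] * i11 + dNdeta[a] * i21;
        g.dNdX[((size_t)eg * 4 + q) * 8 + 2 * a + 1] = dNdxi[a] * i12 + dNdeta[a] * i22;
      }
    }
  }
}

// assemble internal forces; returns false on inversion (bad element in *bad)
static bool assemble_forces(const Grid& g, const std::vector<double>& u,
                            double th_ctx, double th_sub, double k_ratio,
                            std::vector<double>& f, std::vector<double>& gpstress,
                            double& IE, int* bad) {
  std::fill(f.begin(), f.end(), 0.0);
  IE = 0.0;
  int n[4];
  for (int e = 0; e < g.nel; ++e) {
    g.enodes(e, n);
    double ux[4], uy[4];
    for (int a = 0; a < 4; ++a) { ux[a] = u[2 * n[a]]; uy[a] = u[2 * n[a] + 1]; }
    double mu = g.mu[e], kb = k_ratio * mu;
    double gx, gy, gz, dFg;
    growth_diag(g.region[e], th_ctx, th_sub, gx, gy, gz, dFg);
    int eg = g.geo(e);
    double Fq[4][4];
    double Jbar = 0.0, Vref = 0.0;
    for (int q = 0; q < 4; ++q) {
      const double* dN = &g.dNdX[((size_t)eg * 4 + q) * 8];
      double F11 = 1, F12 = 0, F21 = 0, F22 = 1;
      for (int a = 0; a < 4; ++a) {
        F11 += ux[a] * dN[2 * a];  F12 += ux[a] * dN[2 * a + 1];
        F21 += uy[a] * dN[2 * a];  F22 += uy[a] * dN[2 * a + 1];
      }
      Fq[q][0] = F11; Fq[q][1] = F12; Fq[q][2] = F21; Fq[q][3] = F22;
      double dV = g.detJ0[(size_t)eg * 4 + q];
      Jbar += elastic_J(F11, F12, F21, F22, gx, gy, gz) * dV;
      Vref += dV;
    }
    Jbar /= Vref;
    for (int q = 0; q < 4; ++q) {
      const double* dN = &g.dNdX[((size_t)eg * 4 + q) * 8];
      double F11 = Fq[q][0], F12 = Fq[q][1], F21 = Fq[q][2], F22 = Fq[q][3];
      StressOut o;
      if (!stress_point(F11, F12, F21, F22, gx, gy, gz, mu, kb, o, Jbar)) {
        *bad = e; return false;
      }
      double dV = g.detJ0[(size_t)eg * 4 + q];
      IE += o.W * dFg * dV;
      // P = J T F^{-T} = T adj(F)^T
      double P11 = o.T11 * F22 - o.T12 * F12;
      double P12 = -o.T11 * F21 + o.T12 * F11;
      double P21 = o.T12 * F22 - o.T22 * F12;
      double P22 = -o.T12 * F21 + o.T22 * F11;
      for (int a = 0; a < 4; ++a) {
        f[2 * n[a]]     += (P11 * dN[2 * a] + P12 * dN[2 * a + 1]) * dV;
        f[2 * n[a] + 1] += (P21 * dN[2 * a] + P22 * dN[2 * a + 1]) * dV;
      }
      size_t si = ((size_t)e * 4 + q) * 3;
      gpstress[si] = o.T11; gpstress[si + 1] = o.T22; gpstress[si + 2] = o.T12;
    }
  }
  return true;
}

// lumped mass from reference element areas
static void lumped_mass(const Grid& g, double rho, std::vector<double>& m) {
  m.assign(g.nnode, 0.0);
  int n[4];
  for (int e = 0; e < g.nel; ++e) {
    g.enodes(e, n);
    double A = 0;
    for (int q = 0; q < 4; ++q) A += g.detJ0[(size_t)g.geo(e) * 4 + q];
    for (int a = 0; a < 4; ++a) m[n[a]] += rho * A / 4.0;
  }
}

// deformed position of reference point (bilinear in its cell)
static inline int cell_of(const Grid& g, double X, double Y) {
  int i = (int)std::floor(X / g.es); if (i < 0) i = 0; if (i >= g.nex) i = g.nex - 1;
  int j = (int)std::floor(Y / g.es); if (j < 0) j = 0; if (j >= g.ney) j = g.ney - 1;
  return j * g.nex + i;
}

static void def_map(const Grid& g, const std::vector<double>& u,
                    double X, double Y, double* x, double* F /*2x2 or NULL*/) {
  int e = cell_of(g, X, Y);
  int i = e % g.nex, j = e / g.nex;
  double xi = 2.0 * (X - i * g.es) / g.es - 1.0;
  double eta = 2.0 * (Y - j * g.es) / g.es - 1.0;
  int n[4]; g.enodes(e, n);
  double N[4]; shape_N(xi, eta, N);
  x[0] = 0; x[1] = 0;
  for (int a = 0; a < 4; ++a) {
    // deformed nodal position = unperturbed reference lattice + u ... but with
    // perturbed meshes the reference is g.X; use g.X + u always
    x[0] += N[a] * (g.X[2 * n[a]] + u[2 * n[a]]);
    x[1] += N[a] * (g.X[2 * n[a] + 1] + u[2 * n[a] + 1]);
  }
  if (F) {
    double dNdxi[4], dNdeta[4];
    shape_dxi(xi, eta, dNdxi, dNdeta);
    double s = 2.0 / g.es;  // regular lattice mapping (agents require perturb=0)
    F[0] = 0; F[1] = 0; F[2] = 0; F[3] = 0;
    for (int a = 0; a < 4; ++a) {
      double dNdx = dNdxi[a] * s, dNdy = dNdeta[a] * s;
      F[0] += (g.X[2 * n[a]] + u[2 * n[a]]) * dNdx;
      F[1] += (g.X[2 * n[a]] + u[2 * n[a]]) * dNdy;
      F[2] += (g.X[2 * n[a] + 1] + u[2 * n[a] + 1]) * dNdx;
      F[3] += (g.X[2 * n[a] + 1] + u[2 * n[a] + 1]) * dNdy;
    }
  }
}

// Newton pull-back of a deformed-frame point to reference coordinates
static bool pull_back(const Grid& g, const std::vector<double>& u,
                      double xt, double yt, double& X, double& Y) {
  double tol = 1e-10 * g.es;
  for (int it = 0; it < 60; ++it) {
    double x[2], F[4];
    def_map(g, u, X, Y, x, F);
    double rx = xt - x[0], ry = yt - x[1];
    if (std::fabs(rx) < tol && std::fabs(ry) < tol) return true;
    double dJ = F[0] * F[3] - F[1] * F[2];
    if (std::fabs(dJ) < 1e-14) return false;
    double dX = (F[3] * rx - F[1] * ry) / dJ;
    double dY = (-F[2] * rx + F[0] * ry) / dJ;
    // damp large updates to stay near the walk path
    double mx = 2.0 * g.es;
    if (std::fabs(dX) > mx) dX = dX > 0 ? mx : -mx;
    if (std::fabs(dY) > mx) dY = dY > 0 ? mx : -mx;
    X += dX; Y += dY;
    if (X < 0) X = 0; if (X > g.w) X = g.w;
    if (Y < 0) Y = 0; if (Y > g.h + g.tc) Y = g.h + g.tc;
  }
  return false;
}

// cells traversed by a reference-frame segment (regular lattice DDA)
static void traverse_cells(const Grid& g, double x0, double y0,
                           double x1, double y1, std::vector<int>& out) {
  out.clear();
  double es = g.es;
  int i = (int)std::floor(x0 / es), j = (int)std::floor(y0 / es);
  int i1 = (int)std::floor(x1 / es), j1 = (int)std::floor(y1 / es);
  auto clampi = [&](int v, int hi) { return v < 0 ? 0 : (v > hi ? hi : v); };
  i = clampi(i, g.nex - 1); j = clampi(j, g.ney - 1);
  i1 = clampi(i1, g.nex - 1); j1 = clampi(j1, g.ney - 1);
  double dx = x1 - x0, dy = y1 - y0;
  int si = dx > 0 ? 1 : -1, sj = dy > 0 ? 1 : -1;
  double tMaxX = (dx != 0) ? (((dx > 0 ? (i + 1) : i) * es - x0) / dx) : 1e30;
  double tMaxY = (dy != 0) ? (((dy > 0 ? (j + 1) : j) * es - y0) / dy) : 1e30;
  double tDx = (dx != 0) ? std::fabs(es / dx) : 1e30;
  double tDy = (dy != 0) ? std::fabs(es / dy) : 1e30;
  out.push_back(j * g.nex + i);
  int guard = 4 * (g.nex + g.ney);
  while ((i != i1 || j != j1) && guard-- > 0) {
    if (tMaxX < tMaxY) { i += si; tMaxX += tDx; } else { j += sj; tMaxY += tDy; }
    if (i < 0 || i >= g.nex || j < 0 || j >= g.ney) break;
    out.push_back(j * g.nex + i);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_segment_cells(double w, double h, double tc, double es,
                                double x0, double y0, double x1, double y1) {
  Grid g; grid_build(g, w, h, tc, es, 0.0);
  std::vector<int> cells;
  traverse_cells(g, x0, y0, x1, y1, cells);
  return IntegerVector(cells.begin(), cells.end());
}

// ---------------------------------------------------------------------------
// R-facing single evaluations (internal forces on a supplied state)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_internal_forces(double w, double h, double tc, double es,
                         double perturb, NumericVector u,
                         IntegerVector region, NumericVector mu_el,
                         double th_ctx, double th_sub, double k_ratio) {
  Grid g; grid_build(g, w, h, tc, es, perturb);
  if ((int)region.size() != g.nel) stop("region length != n elements");
  for (int e = 0; e < g.nel; ++e) g.region[e] = region[e];
  g.mu.assign(mu_el.begin(), mu_el.end());
  std::vector<double> uu(u.begin(), u.end()), f(2 * g.nnode);
  std::vector<double> gps((size_t)g.nel * 12);
  double IE = 0; int bad = -1;
  if (!assemble_forces(g, uu, th_ctx, th_sub, k_ratio, f, gps, IE, &bad))
    stop("element inversion in element %d (1-based %d)", bad, bad + 1);
  NumericMatrix S(g.nel * 4, 3);
  for (int r = 0; r < g.nel * 4; ++r)
    for (int c = 0; c < 3; ++c) S(r, c) = gps[(size_t)r * 3 + c];
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["internal_energy"] = IE, _["gp_stress"] = S);
}

// ---------------------------------------------------------------------------
// Coupled run
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run(List cfg) {
  // geometry / discretisation
  double w = cfg["w"], h = cfg["h"], tc = cfg["t_c"], es = cfg["elem_size"];
  double perturb = cfg["perturb"];
  // material
  double mu_s = cfg["mu_s"];
  double mu_c = mu_s * as<double>(cfg["mu_c_over_mu_s"]);
  double mu_f = mu_s * as<double>(cfg["mu_f_over_mu_s"]);
  double k_ratio = cfg["k_over_mu"];
  // growth
  double G_ctx = cfg["G_ctx"];
  double growth_ratio = cfg["growth_ratio"];
  double G_sub = G_ctx / growth_ratio;
  bool expo = as<std::string>(cfg["growth_kinetics"]) == "exponential";
  // time stepping
  int agent_steps = cfg["agent_steps"];
  int substeps = cfg["substeps"];
  double t_end = 1.0 / G_ctx;       // T = G_ctx * t runs over [0, 1]
  double dt_agent = t_end / agent_steps;
  double dt = dt_agent / substeps;
  double cfl = cfg["cfl"];
  double damping = cfg["damping"];  // 1/day, mass-proportional
  // agents
  int n_fibers = cfg["n_fibers"];
  double seed = cfg["seed"];
  double t_star = cfg["t_star"];
  double noise_std = cfg["noise_std"];
  double G_axn = cfg["G_axn"];
  double a_rate = cfg["a"];
  double sigma0 = cfg["sigma_0"];
  double seed_band = cfg["seed_band"];
  bool reorient = cfg["reorientation_enabled"];
  bool clampg = cfg["clamp_negative_growth"];
  double degen_tol = cfg["degenerate_tol"];

  if (perturb > 0.0 && n_fibers > 0)
    stop("node perturbation is supported only for agent-free runs");

  Grid g; grid_build(g, w, h, tc, es, perturb);
  g.mu.assign(g.nel, mu_s);
  for (int e = 0; e < g.nel; ++e) if (g.region[e] == 1) g.mu[e] = mu_c;

  // automatic mass scaling: density chosen so the dilatational wave CFL
  // matches the requested substep
  double mu_max = std::max(mu_c, std::max(mu_s, mu_f));
  double M = (k_ratio + 4.0 / 3.0) * mu_max;
  double rho = M * (dt / (cfl * es)) * (dt / (cfl * es));

  std::vector<double> u(2 * g.nnode, 0.0), v(2 * g.nnode, 0.0), m;
  lumped_mass(g, rho, m);
  std::vector<double> f(2 * g.nnode), gps((size_t)g.nel * 12, 0.0);

  // agents
  std::vector<double> agX(n_fibers), agY(n_fibers), agTh(n_fibers),
      agLen(n_fibers, 0.0);
  std::vector<int> agStatus(n_fibers, 0);  // 0 growing 1 settled 2 stalled
  std::vector<uint64_t> agRng(n_fibers);
  for (int i = 0; i < n_fibers; ++i) {
    uint64_t s = mix_seed((uint64_t)seed, (uint64_t)(i + 1));
    agX[i] = sm64_unif(s) * w;
    agY[i] = sm64_unif(s) * seed_band;
    agTh[i] = M_PI / 2.0 + (2.0 * sm64_unif(s) - 1.0) * (M_PI / 2.0) * 0.10;
    agRng[i] = s;
  }

  // records
  NumericMatrix traj(n_fibers > 0 ? n_fibers * agent_steps : 0, 7);
  NumericMatrix series(agent_steps, 10);
  NumericMatrix pial_x(agent_steps, g.nnx), pial_y(agent_steps, g.nnx);
  double th_ctx = 1.0, th_sub = 1.0, t = 0.0;
  double IE = 0.0, KE = 0.0;
  std::string abort_reason = "";
  int abort_elem = -1;
  std::vector<int> conv_cells;
  double wm_area0 = w * h;  (void)wm_area0;
  int n_converted = 0;

  bool aborted = false;
  int steps_done = 0;
  for (int k = 0; k < agent_steps && !aborted; ++k) {
    // ---- FE substeps (growth advances continuously) ----
    for (int s = 0; s < substeps; ++s) {
      if (expo) { th_ctx += G_ctx * th_ctx * dt; th_sub += G_sub * th_sub * dt; }
      else      { th_ctx += G_ctx * dt;          th_sub += G_sub * dt; }
      int bad = -1;
      if (!assemble_forces(g, u, th_ctx, th_sub, k_ratio, f, gps, IE, &bad)) {
        abort_reason = "element_inversion"; abort_elem = bad; aborted = true; break;
      }
      double damp = 1.0 / (1.0 + damping * dt);
      KE = 0.0;
      for (int nd = 0; nd < g.nnode; ++nd) {
        double inv_m = 1.0 / m[nd];
        double vx = (v[2 * nd] - dt * f[2 * nd] * inv_m) * damp;
        double vy = (v[2 * nd + 1] - dt * f[2 * nd + 1] * inv_m) * damp;
        int i = nd % g.nnx, j = nd / g.nnx;
        if (i == 0 || i == g.nnx - 1) vx = 0.0;  // symmetric walls
        if (j == 0) vy = 0.0;                    // fixed base
        v[2 * nd] = vx; v[2 * nd + 1] = vy;
        u[2 * nd] += dt * vx; u[2 * nd + 1] += dt * vy;
        KE += 0.5 * m[nd] * (vx * vx + vy * vy);
      }
      t += dt;
      if (!std::isfinite(KE) || (IE > 1e-9 && KE > 10.0 * IE)) {
        abort_reason = "instability"; aborted = true; break;
      }
    }
    if (aborted) break;

    // ---- agent step ----
    for (int i = 0; i < n_fibers; ++i) {
      double eps = sm64_norm(agRng[i]);  // one draw per agent per step, always
      if (agStatus[i] == 0) {
        int e = cell_of(g, agX[i], agY[i]);
        // nearest gauss point stress
        int ei = e % g.nex, ej = e / g.nex;
        double xi = 2.0 * (agX[i] - ei * es) / es - 1.0;
        double eta = 2.0 * (agY[i] - ej * es) / es - 1.0;
        int q = (xi > 0 ? 1 : 0) + (eta > 0 ? 2 : 0);
        // gp order: (-,-),(+,-),(+,+),(-,+) -> q index mapping
        int qmap[4] = {0, 1, 3, 2};
        size_t si = ((size_t)e * 4 + qmap[q]) * 3;
        double T11 = gps[si], T22 = gps[si + 1], T12 = gps[si + 2];
        agTh[i] += noise_std * eps;
        // principal in-plane
        double tr2 = 0.5 * (T11 + T22);
        double disc = std::sqrt(0.25 * (T11 - T22) * (T11 - T22) + T12 * T12);
        double s1 = tr2 + disc, s2 = tr2 - disc;
        bool degen = (s1 - s2) <= degen_tol * std::max(std::fabs(s1), mu_s);
        if (reorient && !degen && s1 >= 0.0) {
          double phi = 0.5 * std::atan2(2.0 * T12, T11 - T22);
          double dxr = std::cos(phi), dyr = std::sin(phi);
          double ca = std::cos(agTh[i]), sa = std::sin(agTh[i]);
          if (ca * dxr + sa * dyr < 0) { dxr = -dxr; dyr = -dyr; }
          double gap = std::atan2(ca * dyr - sa * dxr, ca * dxr + sa * dyr);
          double omega = (M_PI / (2.0 * t_star)) * std::fabs(std::sin(gap));
          double rot = std::min(omega, std::fabs(gap));
          agTh[i] += (gap >= 0 ? rot : -rot);
        }
        double ca = std::cos(agTh[i]), sa = std::sin(agTh[i]);
        double sig = ca * ca * T11 + 2.0 * ca * sa * T12 + sa * sa * T22;
        double dG = a_rate * (sig - sigma0) + G_axn;
        if (clampg && dG < 0) dG = 0;
        double dL = dG * dt_agent;
        double xd[2];
        def_map(g, u, agX[i], agY[i], xd, NULL);
        double xn = xd[0] + dL * ca, yn = xd[1] + dL * sa;
        if (xn < 0 || xn > w || yn < 0) {
          agStatus[i] = 2;  // stalled at a wall
        } else {
          double Xn = agX[i], Yn = agY[i];
          if (!pull_back(g, u, xn, yn, Xn, Yn)) {
            agStatus[i] = 2;
          } else {
            traverse_cells(g, agX[i], agY[i], Xn, Yn, conv_cells);
            for (int c : conv_cells)
              if (g.region[c] == 0) {
                g.region[c] = 2; g.mu[c] = mu_f; ++n_converted;
              }
            agX[i] = Xn; agY[i] = Yn; agLen[i] += dL;
            if (Yn >= h) agStatus[i] = 1;  // reached the interface: settled
          }
        }
        if (n_fibers > 0) {
          int r = i * agent_steps + k;
          traj(r, 0) = i + 1; traj(r, 1) = k + 1;
          double xf[2]; def_map(g, u, agX[i], agY[i], xf, NULL);
          traj(r, 2) = xf[0]; traj(r, 3) = xf[1];
          traj(r, 4) = agTh[i]; traj(r, 5) = sig; traj(r, 6) = agStatus[i];
        }
      } else if (n_fibers > 0) {
        int r = i * agent_steps + k;
        traj(r, 0) = i + 1; traj(r, 1) = k + 1;
        double xf[2]; def_map(g, u, agX[i], agY[i], xf, NULL);
        traj(r, 2) = xf[0]; traj(r, 3) = xf[1];
        traj(r, 4) = agTh[i]; traj(r, 5) = NA_REAL; traj(r, 6) = agStatus[i];
      }
    }

    // ---- records ----
    double af = 0, ae = 0;
    int nset = 0, nstall = 0;
    {
      int n[4];
      for (int e = 0; e < g.nel; ++e) {
        if (g.region[e] == 1) continue;
        g.enodes(e, n);
        double xs[4], ys[4];
        for (int a = 0; a < 4; ++a) {
          xs[a] = g.X[2 * n[a]] + u[2 * n[a]];
          ys[a] = g.X[2 * n[a] + 1] + u[2 * n[a] + 1];
        }
        double A = 0.5 * std::fabs((xs[2] - xs[0]) * (ys[3] - ys[1]) -
                                   (xs[3] - xs[1]) * (ys[2] - ys[0]));
        if (g.region[e] == 2) af += A; else ae += A;
      }
      for (int i = 0; i < n_fibers; ++i) {
        if (agStatus[i] == 1) ++nset;
        if (agStatus[i] == 2) ++nstall;
      }
    }
    series(k, 0) = t;
    series(k, 1) = G_ctx * t;
    series(k, 2) = KE;
    series(k, 3) = IE;
    series(k, 4) = IE > 0 ? KE / IE : 0.0;
    series(k, 5) = (af + ae) > 0 ? af / (af + ae) : 0.0;
    series(k, 6) = n_converted;
    series(k, 7) = nset;
    series(k, 8) = nstall;
    series(k, 9) = th_ctx;
    for (int i = 0; i < g.nnx; ++i) {
      int nd = g.node(i, g.nny - 1);
      pial_x(k, i) = g.X[2 * nd] + u[2 * nd];
      pial_y(k, i) = g.X[2 * nd + 1] + u[2 * nd + 1];
    }
    steps_done = k + 1;
  }

  NumericMatrix S(g.nel * 4, 3);
  for (int r = 0; r < g.nel * 4; ++r)
    for (int c = 0; c < 3; ++c) S(r, c) = gps[(size_t)r * 3 + c];
  NumericMatrix AG(n_fibers, 5);
  for (int i = 0; i < n_fibers; ++i) {
    AG(i, 0) = agX[i]; AG(i, 1) = agY[i]; AG(i, 2) = agTh[i];
    AG(i, 3) = agLen[i]; AG(i, 4) = agStatus[i];
  }
  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["theta_ctx"] = th_ctx, _["theta_sub"] = th_sub, _["t"] = t,
      _["elem_region"] = IntegerVector(g.region.begin(), g.region.end()),
      _["elem_mu"] = NumericVector(g.mu.begin(), g.mu.end()),
      _["gp_stress"] = S, _["trajectories"] = traj, _["series"] = series,
      _["pial_x"] = pial_x, _["pial_y"] = pial_y, _["agents"] = AG,
      _["rho"] = rho, _["dt"] = dt, _["steps_done"] = steps_done,
      _["aborted"] = aborted, _["abort_reason"] = abort_reason,
      _["abort_elem"] = abort_elem + 1);
}

// deformed-frame point probe used by probe_stress(); brute force with a
// bounding-box prefilter over deformed quads
// [[Rcpp::export]]
List cpp_probe(double w, double h, double tc, double es, double perturb,
               NumericVector u, NumericMatrix pts) {
  Grid g; grid_build(g, w, h, tc, es, perturb);
  std::vector<double> uu(u.begin(), u.end());
  int np = pts.nrow();
  IntegerVector elem(np);
  NumericMatrix loc(np, 2);
  int n[4];
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1);
    elem[p] = NA_INTEGER;
    for (int e = 0; e < g.nel; ++e) {
      g.enodes(e, n);
      double xs[4], ys[4];
      double xmin = 1e30, xmax = -1e30, ymin = 1e30, ymax = -1e30;
      for (int a = 0; a < 4; ++a) {
        xs[a] = g.X[2 * n[a]] + uu[2 * n[a]];
        ys[a] = g.X[2 * n[a] + 1] + uu[2 * n[a] + 1];
        xmin = std::min(xmin, xs[a]); xmax = std::max(xmax, xs[a]);
        ymin = std::min(ymin, ys[a]); ymax = std::max(ymax, ys[a]);
      }
      double tolb = 1e-9 * es;
      if (px < xmin - tolb || px > xmax + tolb || py < ymin - tolb || py > ymax + tolb)
        continue;
      // point-in-quad by winding (convex or mildly distorted quads)
      bool inside = true;
      for (int a = 0; a < 4; ++a) {
        int b2 = (a + 1) % 4;
        double cr = (xs[b2] - xs[a]) * (py - ys[a]) - (ys[b2] - ys[a]) * (px - xs[a]);
        if (cr < -1e-9 * es * es) { inside = false; break; }
      }
      if (inside) {
        elem[p] = e + 1;
        // local coords by Newton on the bilinear map of this cell
        double X = (e % g.nex + 0.5) * es, Y = (e / g.nex + 0.5) * es;
        pull_back(g, uu, px, py, X, Y);
        loc(p, 0) = X; loc(p, 1) = Y;
        break;
      }
    }
  }
  return List::create(_["elem"] = elem, _["ref"] = loc);
}
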