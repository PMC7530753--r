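// Particle-physics core: neighbour search (inline pair visitor: direct scan
// at desk scales, linked cells for large systems), cubic-spline SPH kernel,
// pairwise force assembly (Tait pressure, artificial viscosity, Hookean
// bonds, tethers, radial contraction, interface repulsion) and the
// velocity-Verlet stepping loop. The tube axis is x; the box is periodic
// along x only.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double dx, double L) {
  if (dx > 0.5 * L) dx -= L;
  else if (dx < -0.5 * L) dx += L;
  return dx;
}

// cubic spline kernel, support radius 2h, 3D normalisation 1/(pi h^3)
static inline double w_cubic(double r, double h) {
  double q = r / h;
  double s = 1.0 / (M_PI * h * h * h);
  if (q < 1.0) return s * (1.0 - 1.5 * q * q + 0.75 * q * q * q);
  if (q < 2.0) { double t = 2.0 - q; return 0.25 * s * t * t * t; }
  return 0.0;
}

// dW/dr
static inline double dw_cubic(double r, double h) {
  double q = r / h;
  double s = 1.0 / (M_PI * h * h * h * h);
  if (q < 1.0) return s * (-3.0 * q + 2.25 * q * q);
  if (q < 2.0) { double t = 2.0 - q; return -0.75 * s * t * t; }
  return 0.0;
}

// Visit every unordered pair with minimum-image distance < cutoff, calling
// f(a, b, dx, dy, dz, r). Direct O(N^2) scan for small N (fast and branch
// free at desk scales); linked-cell grid above that. The cell path needs at
// least 3 cells along the periodic axis so each image pair is seen once.
template <typename F>
static void visit_pairs(const double* px, const double* py, const double* pz,
                        int n, double L, double cutoff, F f) {
  double c2 = cutoff * cutoff;
  if (n < 2) return;
  int ncx = (int)std::floor(L / cutoff);
  bool brute = (n <= 1500) || (ncx < 3);
  if (!brute) {
    double ymin = py[0], ymax = py[0], zmin = pz[0], zmax = pz[0];
    for (int a = 1; a < n; ++a) {
      if (py[a] < ymin) ymin = py[a]; if (py[a] > ymax) ymax = py[a];
      if (pz[a] < zmin) zmin = pz[a]; if (pz[a] > zmax) zmax = pz[a];
    }
    int ncy = std::max(1, (int)std::floor((ymax - ymin) / cutoff));
    int ncz = std::max(1, (int)std::floor((zmax - zmin) / cutoff));
    // guard against degenerate extents (e.g. after a diverging trajectory)
    double ncells = (double)ncx * ncy * ncz;
    if (ncells > 8.0 * n + 1024.0) brute = true;
    if (!brute) {
      double celly = (ymax - ymin) / ncy; if (celly <= 0) celly = 1.0;
      double cellz = (zmax - zmin) / ncz; if (cellz <= 0) cellz = 1.0;
      double cellx = L / ncx;
      std::vector<int> head(ncx * ncy * ncz, -1), nxt(n, -1);
      for (int a = 0; a < n; ++a) {
        int ix = (int)std::floor(px[a] / cellx); if (ix >= ncx) ix = ncx - 1; if (ix < 0) ix = 0;
        int iy = (int)std::floor((py[a] - ymin) / celly); if (iy >= ncy) iy = ncy - 1; if (iy < 0) iy = 0;
        int iz = (int)std::floor((pz[a] - zmin) / cellz); if (iz >= ncz) iz = ncz - 1; if (iz < 0) iz = 0;
        int c = (ix * ncy + iy) * ncz + iz;
        nxt[a] = head[c]; head[c] = a;
      }
      static const int OFF[13][3] = {
        {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1},
        {0,1,-1},{0,1,0},{0,1,1},{0,0,1}};
      for (int ix = 0; ix < ncx; ++ix)
      for (int iy = 0; iy < ncy; ++iy)
      for (int iz = 0; iz < ncz; ++iz) {
        int c = (ix * ncy + iy) * ncz + iz;
        for (int a = head[c]; a >= 0; a = nxt[a]) {
          for (int b = nxt[a]; b >= 0; b = nxt[b]) {
            double ddx = min_image(px[a] - px[b], L);
            double ddy = py[a] - py[b], ddz = pz[a] - pz[b];
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (r2 < c2) f(a, b, ddx, ddy, ddz, std::sqrt(r2));
          }
          for (int o = 0; o < 13; ++o) {
            int jx = ix + OFF[o][0], jy = iy + OFF[o][1], jz = iz + OFF[o][2];
            if (jx >= ncx) jx -= ncx;              // periodic along the axis
            if (jy < 0 || jy >= ncy || jz < 0 || jz >= ncz) continue;
            int cc = (jx * ncy + jy) * ncz + jz;
            for (int b = head[cc]; b >= 0; b = nxt[b]) {
              double ddx = min_image(px[a] - px[b], L);
              double ddy = py[a] - py[b], ddz = pz[a] - pz[b];
              double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (r2 < c2) f(a, b, ddx, ddy, ddz, std::sqrt(r2));
            }
          }
        }
      }
      return;
    }
  }
  for (int a = 0; a < n - 1; ++a) {
    double pxa = px[a], pya = py[a], pza = pz[a];
    for (int b = a + 1; b < n; ++b) {
      double ddx = min_image(pxa - px[b], L);
      double ddy = pya - py[b], ddz = pza - pz[b];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 < c2) f(a, b, ddx, ddy, ddz, std::sqrt(r2));
    }
  }
}

// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix pos, double L, double cutoff) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int a = 0; a < n; ++a) { px[a] = pos(a,0); py[a] = pos(a,1); pz[a] = pos(a,2); }
  std::vector<int> vi, vj;
  std::vector<double> vdx, vdy, vdz, vr;
  visit_pairs(px.data(), py.data(), pz.data(), n, L, cutoff,
              [&](int a, int b, double dx, double dy, double dz, double r) {
    vi.push_back(a + 1); vj.push_back(b + 1);
    vdx.push_back(dx); vdy.push_back(dy); vdz.push_back(dz); vr.push_back(r);
  });
  int m = (int)vi.size();
  IntegerVector I(vi.begin(), vi.end()), J(vj.begin(), vj.end());
  NumericVector D(vr.begin(), vr.end());
  NumericMatrix DX(m, 3);
  for (int k = 0; k < m; ++k) {
    DX(k,0) = vdx[k]; DX(k,1) = vdy[k]; DX(k,2) = vdz[k];
  }
  return List::create(_["i"] = I, _["j"] = J, _["dist"] = D, _["disp"] = DX);
}

// summation density over the supplied particles (self term included)
// [[Rcpp::export]]
NumericVector cpp_summation_density(NumericMatrix pos, NumericVector mass,
                                    double L, double h) {
  int n = pos.nrow();
  NumericVector rho(n);
  for (int a = 0; a < n; ++a) rho[a] = mass[a] * w_cubic(0.0, h);
  std::vector<double> px(n), py(n), pz(n);
  for (int a = 0; a < n; ++a) { px[a] = pos(a,0); py[a] = pos(a,1); pz[a] = pos(a,2); }
  visit_pairs(px.data(), py.data(), pz.data(), n, L, 2.0 * h,
              [&](int a, int b, double, double, double, double r) {
    double w = w_cubic(r, h);
    rho[a] += mass[b] * w;
    rho[b] += mass[a] * w;
  });
  return rho;
}

struct Params {
  double L, h, c0, rho0, a, b;
  bool tait_squared;
  double k_tether, f0, A_rep, r0_rep;
};

static Params read_params(const List& p) {
  Params q;
  q.L = as<double>(p["L"]);
  q.h = as<double>(p["h"]);
  q.c0 = as<double>(p["c0"]);
  q.rho0 = as<double>(p["rho0"]);
  q.a = as<double>(p["a"]);
  q.b = as<double>(p["b"]);
  q.tait_squared = as<bool>(p["tait_squared"]);
  q.k_tether = as<double>(p["k_tether"]);
  q.f0 = as<double>(p["f0"]);
  q.A_rep = as<double>(p["A_rep"]);
  q.r0_rep = as<double>(p["r0_rep"]);
  return q;
}

static inline double tait(double rho, const Params& p) {
  double pref = p.tait_squared ? p.c0 * p.c0 * p.rho0 / 7.0 : p.c0 * p.rho0 / 7.0;
  double q = rho / p.rho0;
  double q2 = q * q;
  return pref * (q2 * q2 * q2 * q - 1.0);
}

struct Terms { bool fluid, cross_visc, repulsive, bonds, tether, contraction, continuity; };

static Terms read_terms(const List& t) {
  Terms q;
  q.fluid = as<bool>(t["fluid"]);
  q.cross_visc = as<bool>(t["cross_visc"]);
  q.repulsive = as<bool>(t["repulsive"]);
  q.bonds = as<bool>(t["bonds"]);
  q.tether = as<bool>(t["tether"]);
  q.contraction = as<bool>(t["contraction"]);
  q.continuity = as<bool>(t["continuity"]);
  return q;
}

// Lower bound applied to fluid densities wherever a density enters a force
// denominator; keeps the viscous rho_ij and P/rho^2 terms finite through
// violent squeezes. See the package vignette, "numerical choices".
static const double RHO_FLOOR_FRAC = 0.1;

// Assemble forces (and, optionally, the continuity-equation density rate).
// phase: 0 = fluid, 1 = solid. slice: 0-based slice id for solids, -1 fluid.
static void forces_impl(const std::vector<double>& px, const std::vector<double>& py,
                        const std::vector<double>& pz,
                        const std::vector<double>& vx, const std::vector<double>& vy,
                        const std::vector<double>& vz,
                        const std::vector<double>& rho, const std::vector<double>& mass,
                        const std::vector<int>& phase, const std::vector<int>& slice,
                        const std::vector<int>& bi, const std::vector<int>& bj,
                        const std::vector<double>& br0, const std::vector<double>& bk,
                        const std::vector<double>& ax, const std::vector<double>& ay,
                        const std::vector<double>& az,
                        const std::vector<bool>& active,
                        const Params& p, const Terms& t,
                        std::vector<double>& fx, std::vector<double>& fy,
                        std::vector<double>& fz, std::vector<double>& drho) {
  int n = (int)px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  std::fill(drho.begin(), drho.end(), 0.0);

  if (t.fluid || t.cross_visc || t.repulsive || t.continuity) {
    double supp = 2.0 * p.h;
    double cutoff = 0.0;
    if (t.fluid || t.cross_visc || t.continuity) cutoff = supp;
    if (t.repulsive && p.r0_rep > cutoff) cutoff = p.r0_rep;
    double rho_floor = RHO_FLOOR_FRAC * p.rho0;

    std::vector<double> pres(n, 0.0), rho_eff(n);
    for (int a = 0; a < n; ++a)
      rho_eff[a] = (phase[a] == 0) ? std::max(rho[a], rho_floor) : p.rho0;
    // Pressures below zero are clamped: the cubic-spline kernel is unstable
    // under tension (particle pairing), and a weakly compressible liquid
    // cavitates rather than sustaining it. See the vignette.
    if (t.fluid)
      for (int a = 0; a < n; ++a)
        if (phase[a] == 0) pres[a] = std::max(0.0, tait(rho_eff[a], p));

    visit_pairs(px.data(), py.data(), pz.data(), n, p.L, cutoff,
                [&](int a, int b, double ddx, double ddy, double ddz, double r) {
      if (r <= 0.0) stop("overlapping particles (pair %d, %d)", a + 1, b + 1);
      bool aw = phase[a] == 0, bw = phase[b] == 0;   // fluid flags
      if (!aw && !bw) return;                        // solid-solid: bonds only
      double inv_r = 1.0 / r;
      if (r < supp) {
        double dvx = vx[a] - vx[b], dvy = vy[a] - vy[b], dvz = vz[a] - vz[b];
        double vdotr = dvx * ddx + dvy * ddy + dvz * ddz;
        double dw = dw_cubic(r, p.h);
        if (aw && bw) {
          if (t.fluid) {
            double rho_ij = rho_eff[a] + rho_eff[b];
            double term = pres[a] / (rho_eff[a] * rho_eff[a]) +
                          pres[b] / (rho_eff[b] * rho_eff[b]) +
                          (-p.a * p.h * (p.c0 / rho_ij) * vdotr /
                           (r * r + p.b * p.h * p.h));
            double f = -mass[a] * mass[b] * term * dw * inv_r;
            fx[a] += f * ddx; fy[a] += f * ddy; fz[a] += f * ddz;
            fx[b] -= f * ddx; fy[b] -= f * ddy; fz[b] -= f * ddz;
          }
          if (t.continuity) {
            double g = dw * vdotr * inv_r;
            drho[a] += mass[b] * g;
            drho[b] += mass[a] * g;
          }
        } else {
          if (t.cross_visc) {
            double rho_ij = rho_eff[a] + rho_eff[b];
            double pi_ab = -p.a * p.h * (p.c0 / rho_ij) * vdotr /
                           (r * r + p.b * p.h * p.h);
            double f = -mass[a] * mass[b] * pi_ab * dw * inv_r;
            fx[a] += f * ddx; fy[a] += f * ddy; fz[a] += f * ddz;
            fx[b] -= f * ddx; fy[b] -= f * ddy; fz[b] -= f * ddz;
          }
          if (t.continuity) {
            // moving-wall contribution to the fluid side's density rate
            double g = dw * vdotr * inv_r;
            if (aw) drho[a] += mass[b] * g;
            else drho[b] += mass[a] * g;
          }
        }
      }
      if (t.repulsive && aw != bw && r < p.r0_rep) {
        double fmag = (p.A_rep * M_PI / p.r0_rep) *
                      std::sin(M_PI * r / p.r0_rep) * inv_r;
        fx[a] += fmag * ddx; fy[a] += fmag * ddy; fz[a] += fmag * ddz;
        fx[b] -= fmag * ddx; fy[b] -= fmag * ddy; fz[b] -= fmag * ddz;
      }
    });
  }

  if (t.bonds) {
    int nb = (int)bi.size();
    for (int k = 0; k < nb; ++k) {
      int a = bi[k], b = bj[k];
      double ddx = min_image(px[a] - px[b], p.L);
      double ddy = py[a] - py[b];
      double ddz = pz[a] - pz[b];
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (r <= 0.0) stop("coincident bonded particles (bond %d)", k + 1);
      double f = -bk[k] * (r - br0[k]) / r;  // negative when stretched: pull together
      fx[a] += f * ddx; fy[a] += f * ddy; fz[a] += f * ddz;
      fx[b] -= f * ddx; fy[b] -= f * ddy; fz[b] -= f * ddz;
    }
  }

  if (t.tether) {
    for (int a = 0; a < n; ++a) {
      if (phase[a] != 1) continue;
      fx[a] += -p.k_tether * (px[a] - ax[a]);
      fy[a] += -p.k_tether * (py[a] - ay[a]);
      fz[a] += -p.k_tether * (pz[a] - az[a]);
    }
  }

  if (t.contraction) {
    for (int a = 0; a < n; ++a) {
      if (phase[a] != 1 || slice[a] < 0 || !active[slice[a]]) continue;
      double rr = std::sqrt(py[a] * py[a] + pz[a] * pz[a]);
      if (rr <= 0.0) continue;              // on-axis: radial direction undefined
      fy[a] += -p.f0 * py[a] / rr;
      fz[a] += -p.f0 * pz[a] / rr;
    }
  }
}

struct State {
  std::vector<double> px, py, pz, vx, vy, vz, rho, mass, ax, ay, az, br0, bk;
  std::vector<int> phase, slice, wind, bi, bj;
  std::vector<bool> active;
};

static State unpack(NumericMatrix pos, NumericMatrix vel, NumericVector rho,
                    IntegerVector wind, NumericVector mass, IntegerVector phase,
                    IntegerVector slice, IntegerVector bond_i,
                    IntegerVector bond_j, NumericVector bond_r0,
                    NumericVector bond_k, NumericMatrix anchors,
                    IntegerVector active_slices) {
  int n = pos.nrow();
  State s;
  s.px.resize(n); s.py.resize(n); s.pz.resize(n);
  s.vx.resize(n); s.vy.resize(n); s.vz.resize(n);
  s.rho.resize(n); s.mass.resize(n);
  s.ax.resize(n); s.ay.resize(n); s.az.resize(n);
  s.phase.resize(n); s.slice.resize(n); s.wind.resize(n);
  for (int a = 0; a < n; ++a) {
    s.px[a] = pos(a,0); s.py[a] = pos(a,1); s.pz[a] = pos(a,2);
    s.vx[a] = vel(a,0); s.vy[a] = vel(a,1); s.vz[a] = vel(a,2);
    s.rho[a] = rho[a]; s.mass[a] = mass[a];
    s.ax[a] = anchors(a,0); s.ay[a] = anchors(a,1); s.az[a] = anchors(a,2);
    s.phase[a] = phase[a]; s.slice[a] = slice[a]; s.wind[a] = wind[a];
  }
  int nb = bond_i.size();
  s.bi.resize(nb); s.bj.resize(nb); s.br0.resize(nb); s.bk.resize(nb);
  for (int k = 0; k < nb; ++k) {
    s.bi[k] = bond_i[k] - 1; s.bj[k] = bond_j[k] - 1;
    s.br0[k] = bond_r0[k]; s.bk[k] = bond_k[k];
  }
  int nsl = 0;
  for (int a = 0; a < n; ++a) if (s.slice[a] >= nsl) nsl = s.slice[a] + 1;
  if (nsl < 10) nsl = 10;
  s.active.assign(nsl, false);
  for (int k = 0; k < active_slices.size(); ++k) s.active[active_slices[k]] = true;
  return s;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, NumericVector rho,
                NumericVector mass, IntegerVector phase, IntegerVector slice,
                IntegerVector bond_i, IntegerVector bond_j,
                NumericVector bond_r0, NumericVector bond_k,
                NumericMatrix anchors, IntegerVector active_slices,
                List params, List terms) {
  int n = pos.nrow();
  Params p = read_params(params);
  Terms t = read_terms(terms);
  IntegerVector wind(n);
  State s = unpack(pos, vel, rho, wind, mass, phase, slice, bond_i, bond_j,
                   bond_r0, bond_k, anchors, active_slices);
  std::vector<double> fx(n), fy(n), fz(n), dr(n);
  forces_impl(s.px, s.py, s.pz, s.vx, s.vy, s.vz, s.rho, s.mass, s.phase,
              s.slice, s.bi, s.bj, s.br0, s.bk, s.ax, s.ay, s.az, s.active,
              p, t, fx, fy, fz, dr);
  NumericMatrix F(n, 3);
  NumericVector drho(n);
  for (int a = 0; a < n; ++a) {
    F(a,0) = fx[a]; F(a,1) = fy[a]; F(a,2) = fz[a]; drho[a] = dr[a];
  }
  return List::create(_["forces"] = F, _["drho"] = drho);
}

// Velocity-Verlet loop with continuity-equation density update.
// Returns the final state, the per-step unwrapped fluid centre of mass, and
// the minimum per-slice mean membrane radius observed over the window.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix pos, NumericMatrix vel, NumericVector rho,
                 IntegerVector wind, NumericVector mass, IntegerVector phase,
                 IntegerVector slice,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_r0, NumericVector bond_k,
                 NumericMatrix anchors, IntegerVector active_slices,
                 List params, List terms, int nsteps, double dt) {
  int n = pos.nrow();
  Params p = read_params(params);
  Terms t = read_terms(terms);
  State s = unpack(pos, vel, rho, wind, mass, phase, slice, bond_i, bond_j,
                   bond_r0, bond_k, anchors, active_slices);
  double rho_floor = RHO_FLOOR_FRAC * p.rho0;

  int nsl = (int)s.active.size();
  std::vector<double> min_rad(nsl, R_PosInf);
  std::vector<int> sl_count(nsl, 0);
  for (int a = 0; a < n; ++a)
    if (s.phase[a] == 1 && s.slice[a] >= 0) sl_count[s.slice[a]]++;

  double mfl = 0.0;
  for (int a = 0; a < n; ++a) if (s.phase[a] == 0) mfl += s.mass[a];
  NumericVector com(nsteps + 1);
  auto com_now = [&]() {
    double acc = 0.0;
    for (int a = 0; a < n; ++a)
      if (s.phase[a] == 0) acc += s.mass[a] * (s.px[a] + s.wind[a] * p.L);
    return acc / mfl;
  };
  auto slice_minrad = [&]() {
    std::vector<double> acc(nsl, 0.0);
    for (int a = 0; a < n; ++a)
      if (s.phase[a] == 1 && s.slice[a] >= 0)
        acc[s.slice[a]] += std::sqrt(s.py[a] * s.py[a] + s.pz[a] * s.pz[a]);
    for (int q = 0; q < nsl; ++q)
      if (sl_count[q] > 0) {
        double m = acc[q] / sl_count[q];
        if (m < min_rad[q]) min_rad[q] = m;
      }
  };

  std::vector<double> fx(n), fy(n), fz(n), dr(n);
  forces_impl(s.px, s.py, s.pz, s.vx, s.vy, s.vz, s.rho, s.mass, s.phase,
              s.slice, s.bi, s.bj, s.br0, s.bk, s.ax, s.ay, s.az, s.active,
              p, t, fx, fy, fz, dr);
  com[0] = com_now();
  slice_minrad();

  for (int st = 0; st < nsteps; ++st) {
    for (int a = 0; a < n; ++a) {
      double hdtm = 0.5 * dt / s.mass[a];
      s.vx[a] += hdtm * fx[a]; s.vy[a] += hdtm * fy[a]; s.vz[a] += hdtm * fz[a];
      if (s.phase[a] == 0) {
        s.rho[a] += 0.5 * dt * dr[a];
        if (s.rho[a] < rho_floor) s.rho[a] = rho_floor;
      }
      s.px[a] += dt * s.vx[a]; s.py[a] += dt * s.vy[a]; s.pz[a] += dt * s.vz[a];
      if (s.px[a] >= p.L) { s.px[a] -= p.L; s.wind[a] += 1; }
      else if (s.px[a] < 0.0) { s.px[a] += p.L; s.wind[a] -= 1; }
    }
    for (int a = 0; a < n; ++a)
      if (!std::isfinite(s.px[a]) || !std::isfinite(s.py[a]) ||
          !std::isfinite(s.pz[a]))
        stop("simulation diverged at step %d (particle %d)", st + 1, a + 1);
    forces_impl(s.px, s.py, s.pz, s.vx, s.vy, s.vz, s.rho, s.mass, s.phase,
                s.slice, s.bi, s.bj, s.br0, s.bk, s.ax, s.ay, s.az, s.active,
                p, t, fx, fy, fz, dr);
    for (int a = 0; a < n; ++a) {
      double hdtm = 0.5 * dt / s.mass[a];
      s.vx[a] += hdtm * fx[a]; s.vy[a] += hdtm * fy[a]; s.vz[a] += hdtm * fz[a];
      if (s.phase[a] == 0) {
        s.rho[a] += 0.5 * dt * dr[a];
        if (s.rho[a] < rho_floor) s.rho[a] = rho_floor;
      }
    }
    com[st + 1] = com_now();
    slice_minrad();
  }

  NumericMatrix P(n, 3), V(n, 3);
  NumericVector R(n);
  IntegerVector W(n);
  for (int a = 0; a < n; ++a) {
    P(a,0) = s.px[a]; P(a,1) = s.py[a]; P(a,2) = s.pz[a];
    V(a,0) = s.vx[a]; V(a,1) = s.vy[a]; V(a,2) = s.vz[a];
    R[a] = s.rho[a]; W[a] = s.wind[a];
  }
  NumericVector MR(nsl);
  for (int q = 0; q < nsl; ++q) MR[q] = min_rad[q];
  return List::create(_["pos"] = P, _["vel"] = V, _["rho"] = R, _["wind"] = W,
                      _["com"] = com, _["min_slice_radius"] = MR);
}
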