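// Incompressible Navier-Stokes on a uniform staggered (MAC) grid with a
// direct-forcing immersed boundary, fractional-step projection, explicit
// low-storage RK3 time integration and a matrix-free conjugate-gradient
// pressure Poisson solve.  Scalar (leukocyte concentration) transport uses
// conservative first-order upwind fluxes with an exponential wall sink.
//
// Conventions:
//   x = axial (index i), y (j), z (k); uniform spacing h in all directions.
//   u faces: (nx+1) x ny x nz at (i*h, (j+.5)h, (k+.5)h)
//   v faces: nx x (ny+1) x nz at ((i+.5)h, j*h, (k+.5)h)
//   w faces: nx x ny x (nz+1) at ((i+.5)h, (j+.5)h, k*h)
//   p cells: nx x ny x nz at cell centers.
//   The signed distance phi is supplied at grid NODES ((nx+1)(ny+1)(nz+1)),
//   negative inside the lumen (fluid), positive in the wall (solid).
//   Planar (2D) runs use nz = 1 with periodic z.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;
typedef std::vector<double> dvec;
typedef std::int64_t i64;

static inline i64 id3(int i, int j, int k, int NI, int NJ) {
  return (i64)i + (i64)NI * ((i64)j + (i64)NJ * (i64)k);
}

// ---------------------------------------------------------------------------
// grid metadata for one staggered component
struct Stag {
  int NI, NJ, NK;     // array dims
  double ox, oy, oz;  // position offsets in units of h
};

struct Box {
  int nx, ny, nz;
  double h;
  bool px, pz;  // periodic in x / z
};

// trilinear sample of a staggered array at physical point (x,y,z).
// Non-periodic directions clamp the stencil to the array bounds.
static double tri_sample(const dvec& a, const Stag& S, const Box& G,
                         double x, double y, double z) {
  double gx = x / G.h - S.ox, gy = y / G.h - S.oy, gz = z / G.h - S.oz;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (G.px) { i = ((i % G.nx) + G.nx) % G.nx; }
        else { i = std::min(std::max(i, 0), S.NI - 1); }
        if (G.pz && S.NK == G.nz) { k = ((k % G.nz) + G.nz) % G.nz; }
        else { k = std::min(std::max(k, 0), S.NK - 1); }
        j = std::min(std::max(j, 0), S.NJ - 1);
        double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
        out += wgt * a[id3(i, j, k, S.NI, S.NJ)];
      }
  return out;
}

// triquadratic (3x3x3 Lagrange) sample: third-order accurate, used for
// immersed-boundary probes where the trilinear low bias on concave shear
// profiles is measurable
static double tri_sample_q(const dvec& a, const Stag& S, const Box& G,
                           double x, double y, double z) {
  double gx = x / G.h - S.ox, gy = y / G.h - S.oy, gz = z / G.h - S.oz;
  int ic = (int)std::floor(gx + 0.5), jc = (int)std::floor(gy + 0.5),
      kc = (int)std::floor(gz + 0.5);
  double fx = gx - ic, fy = gy - jc, fz = gz - kc;  // in [-0.5, 0.5]
  double wx[3] = {0.5*fx*(fx-1), (1-fx)*(1+fx), 0.5*fx*(fx+1)};
  double wy[3] = {0.5*fy*(fy-1), (1-fy)*(1+fy), 0.5*fy*(fy+1)};
  double wz[3] = {0.5*fz*(fz-1), (1-fz)*(1+fz), 0.5*fz*(fz+1)};
  double out = 0.0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int i = ic + di, j = jc + dj, k = kc + dk;
        if (G.px) i = ((i % G.nx) + G.nx) % G.nx;
        else i = std::min(std::max(i, 0), S.NI - 1);
        if (G.pz && S.NK == G.nz) k = ((k % G.nz) + G.nz) % G.nz;
        else k = std::min(std::max(k, 0), S.NK - 1);
        j = std::min(std::max(j, 0), S.NJ - 1);
        out += wx[di+1] * wy[dj+1] * wz[dk+1] * a[id3(i, j, k, S.NI, S.NJ)];
      }
  return out;
}

// phi sampled at nodes: (nx+1)x(ny+1)x(nz+1), offsets (0,0,0)
static double phi_at(const dvec& phi, const Box& G, double x, double y,
                     double z) {
  Stag S;
  S.NI = G.nx + 1; S.NJ = G.ny + 1; S.NK = G.nz + 1;
  S.ox = S.oy = S.oz = 0.0;
  return tri_sample(phi, S, G, x, y, z);
}

static void phi_grad(const dvec& phi, const Box& G, double x, double y,
                     double z, double* g) {
  double e = 0.5 * G.h;
  g[0] = (phi_at(phi, G, x + e, y, z) - phi_at(phi, G, x - e, y, z)) / (2 * e);
  g[1] = (phi_at(phi, G, x, y + e, z) - phi_at(phi, G, x, y - e, z)) / (2 * e);
  g[2] = (phi_at(phi, G, x, y, z + e) - phi_at(phi, G, x, y, z - e)) / (2 * e);
  if (G.nz == 1) g[2] = 0.0;
}

// ---------------------------------------------------------------------------
// face classification for direct forcing
//   type 0 = regular fluid, 1 = forced (within h inside the wall surface),
//   2 = solid, 3 = ghost (just outside the wall; mirror extension)
struct Forcing {
  std::vector<unsigned char> type;
  dvec px_, py_, pz_;     // probe 1 (forced) or mirror (ghost) point
  dvec qx_, qy_, qz_;     // probe 2 (forced faces only)
  dvec fac, fac2;         // quadratic no-slip weights of the two probes
};

static void classify(const dvec& phi, const Box& G, const Stag& S,
                     Forcing& F) {
  i64 n = (i64)S.NI * S.NJ * S.NK;
  F.type.assign(n, 0);
  F.px_.assign(n, 0.0); F.py_.assign(n, 0.0); F.pz_.assign(n, 0.0);
  F.qx_.assign(n, 0.0); F.qy_.assign(n, 0.0); F.qz_.assign(n, 0.0);
  F.fac.assign(n, 0.0); F.fac2.assign(n, 0.0);
  for (int k = 0; k < S.NK; ++k)
    for (int j = 0; j < S.NJ; ++j)
      for (int i = 0; i < S.NI; ++i) {
        i64 q = id3(i, j, k, S.NI, S.NJ);
        double x = (i + S.ox) * G.h, y = (j + S.oy) * G.h,
               z = (k + S.oz) * G.h;
        double ph = phi_at(phi, G, x, y, z);
        double g[3];
        phi_grad(phi, G, x, y, z, g);
        double gn = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
        if (ph >= 0.0) {
          // just outside the wall: ghost extension of the near-wall
          // quadratic profile (zero at the wall, probes one and two
          // spacings inside), so stencils straddling the interface see
          // the no-slip profile rather than a hard zero
          F.type[q] = 2;
          if (ph < 0.9 * G.h && gn > 1e-12) {
            double nx_ = -g[0]/gn, ny_ = -g[1]/gn, nz_ = -g[2]/gn;
            // wall point is ph outward along the normal from the face
            double p1x = x + (ph + G.h)*nx_, p1y = y + (ph + G.h)*ny_,
                   p1z = z + (ph + G.h)*nz_;
            double p2x = x + (ph + 2*G.h)*nx_, p2y = y + (ph + 2*G.h)*ny_,
                   p2z = z + (ph + 2*G.h)*nz_;
            if (phi_at(phi, G, p1x, p1y, p1z) < 0.0 &&
                phi_at(phi, G, p2x, p2y, p2z) < 0.0) {
              F.type[q] = 3;
              F.px_[q] = p1x; F.py_[q] = p1y; F.pz_[q] = p1z;
              F.qx_[q] = p2x; F.qy_[q] = p2y; F.qz_[q] = p2z;
              double d1 = G.h, d2 = 2*G.h, xx = -ph;
              double den = d1 * d2 * (d2 - d1);
              F.fac[q]  = d2 * xx * (d2 - xx) / den;
              F.fac2[q] = d1 * xx * (xx - d1) / den;
            }
          }
          continue;
        }
        if (ph > -G.h) {
          if (gn < 1e-12) { F.type[q] = 0; continue; }
          double nx_ = -g[0]/gn, ny_ = -g[1]/gn, nz_ = -g[2]/gn;
          // probes one and two spacings deeper along the inward normal;
          // quadratic profile through the wall (zero) and both probes,
          // evaluated back at the face: exact for parabolic shear layers
          double p1x = x + nx_*G.h, p1y = y + ny_*G.h, p1z = z + nz_*G.h;
          double p2x = x + 2*nx_*G.h, p2y = y + 2*ny_*G.h, p2z = z + 2*nz_*G.h;
          if (phi_at(phi, G, p1x, p1y, p1z) >= 0.0 ||
              phi_at(phi, G, p2x, p2y, p2z) >= 0.0) {
            F.type[q] = 2;
            continue;
          }
          F.type[q] = 1;
          F.px_[q] = p1x; F.py_[q] = p1y; F.pz_[q] = p1z;
          F.qx_[q] = p2x; F.qy_[q] = p2y; F.qz_[q] = p2z;
          double d = -ph, d1 = d + G.h, d2 = d + 2*G.h;
          double den = d1 * d2 * (d2 - d1);
          F.fac[q]  = d2 * d * (d2 - d) / den;
          F.fac2[q] = d1 * d * (d - d1) / den;
        }
      }
}

// ---------------------------------------------------------------------------
// precompiled forcing lists: stencil indices/weights frozen at setup
struct FaceOps {
  std::vector<i64> solid;
  std::vector<i64> forced;
  std::vector<i64> fsten_idx;  // 54 per forced face (27 per probe)
  dvec fsten_w;                // quadratic weights x fac folded in
  std::vector<i64> ghost;
  std::vector<i64> gsten_idx;  // 8 per ghost face
  dvec gsten_w;
};

static void build_sten_q(const Stag& S, const Box& G, double x, double y,
                         double z, double fac, std::vector<i64>& idx,
                         dvec& w) {
  double gx = x / G.h - S.ox, gy = y / G.h - S.oy, gz = z / G.h - S.oz;
  int ic = (int)std::floor(gx + 0.5), jc = (int)std::floor(gy + 0.5),
      kc = (int)std::floor(gz + 0.5);
  double fx = gx - ic, fy = gy - jc, fz = gz - kc;
  double wx[3] = {0.5*fx*(fx-1), (1-fx)*(1+fx), 0.5*fx*(fx+1)};
  double wy[3] = {0.5*fy*(fy-1), (1-fy)*(1+fy), 0.5*fy*(fy+1)};
  double wz[3] = {0.5*fz*(fz-1), (1-fz)*(1+fz), 0.5*fz*(fz+1)};
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int i = ic + di, j = jc + dj, k = kc + dk;
        if (G.px) i = ((i % G.nx) + G.nx) % G.nx;
        else i = std::min(std::max(i, 0), S.NI - 1);
        if (G.pz && S.NK == G.nz) k = ((k % G.nz) + G.nz) % G.nz;
        else k = std::min(std::max(k, 0), S.NK - 1);
        j = std::min(std::max(j, 0), S.NJ - 1);
        idx.push_back(id3(i, j, k, S.NI, S.NJ));
        w.push_back(fac * wx[di+1] * wy[dj+1] * wz[dk+1]);
      }
}

static void build_faceops(const Forcing& F, const Stag& S, const Box& G,
                          FaceOps& O) {
  i64 n = (i64)S.NI * S.NJ * S.NK;
  for (i64 q = 0; q < n; ++q) {
    if (F.type[q] == 2) O.solid.push_back(q);
    else if (F.type[q] == 1) {
      O.forced.push_back(q);
      build_sten_q(S, G, F.px_[q], F.py_[q], F.pz_[q], F.fac[q],
                   O.fsten_idx, O.fsten_w);
      build_sten_q(S, G, F.qx_[q], F.qy_[q], F.qz_[q], F.fac2[q],
                   O.fsten_idx, O.fsten_w);
    } else if (F.type[q] == 3) {
      O.ghost.push_back(q);
      build_sten_q(S, G, F.px_[q], F.py_[q], F.pz_[q], F.fac[q],
                   O.gsten_idx, O.gsten_w);
      build_sten_q(S, G, F.qx_[q], F.qy_[q], F.qz_[q], F.fac2[q],
                   O.gsten_idx, O.gsten_w);
    }
  }
}

struct Solver {
  Box G;
  Stag Su, Sv, Sw, Sp;
  dvec phi;
  dvec u, v, w, p;
  dvec qu, qv, qw;     // RK3 registers
  dvec ru, rv, rw;     // RHS scratch
  dvec pois_b, pois_x, pois_r, pois_d, pois_q;
  Forcing Fu, Fv, Fw;
  FaceOps Ou, Ov, Ow;
  std::vector<unsigned char> cellFluid;  // 1 if cell center phi < 0
  dvec inletProf;      // ny*nz, u at i=0 normalized to bulk 1
  double rho, mu, nu;
  double dt;
  // waveform (periodic linear interpolation)
  dvec wf_t, wf_u;
  double wf_T;
  double cg_rtol;
  int cg_maxit;
  double div_max_last;
  int cg_iters_last;
  double Ain;          // fluid inlet area (m^2)
  double Asec;         // section fluid area for periodic bulk forcing
  i64 nFluidU;         // number of type-0 u faces (periodic forcing)
  double uconv_min;

  double waveform(double t) const {
    if (wf_t.size() == 1) return wf_u[0];
    // note: avoid std::fmod (pulls a glibc-2.38-versioned symbol)
    double tm = t - wf_T * std::floor(t / wf_T);
    size_t n = wf_t.size();
    for (size_t m = 1; m < n; ++m) {
      if (tm <= wf_t[m] + 1e-15) {
        double f = (tm - wf_t[m-1]) / (wf_t[m] - wf_t[m-1]);
        return wf_u[m-1] + f * (wf_u[m] - wf_u[m-1]);
      }
    }
    return wf_u[n-1];
  }

  // -- boundary conditions on the box -------------------------------------
  void applyBC(double t) {
    int nx = G.nx, ny = G.ny, nz = G.nz;
    if (!G.px) {
      // inlet: prescribed parabolic profile scaled by bulk waveform
      double Ub = waveform(t);
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          u[id3(0, j, k, Su.NI, Su.NJ)] = Ub * inletProf[j + (i64)ny * k];
    } else {
      // mirror periodic face
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          u[id3(nx, j, k, Su.NI, Su.NJ)] = u[id3(0, j, k, Su.NI, Su.NJ)];
    }
    // box transverse walls lie in the solid; clamp to zero
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < G.nx; ++i) {
        v[id3(i, 0, k, Sv.NI, Sv.NJ)] = 0.0;
        v[id3(i, ny, k, Sv.NI, Sv.NJ)] = 0.0;
      }
    if (!G.pz) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < G.nx; ++i) {
          w[id3(i, j, 0, Sw.NI, Sw.NJ)] = 0.0;
          w[id3(i, j, nz, Sw.NI, Sw.NJ)] = 0.0;
        }
    } else {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < G.nx; ++i)
          w[id3(i, j, nz, Sw.NI, Sw.NJ)] = w[id3(i, j, 0, Sw.NI, Sw.NJ)];
    }
  }

  void outletConvective(double dtb, double t) {
    if (G.px) return;
    int nx = G.nx, ny = G.ny, nz = G.nz;
    double Uc = std::max(waveform(t), uconv_min);
    double Qin = 0.0, Qout = 0.0;
    i64 nOutFluid = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        i64 q0 = id3(0, j, k, Su.NI, Su.NJ);
        if (Fu.type[q0] <= 1) Qin += u[q0];
        i64 qn = id3(nx, j, k, Su.NI, Su.NJ);
        i64 qm = id3(nx - 1, j, k, Su.NI, Su.NJ);
        if (Fu.type[qn] >= 2) { continue; }
        u[qn] -= dtb * Uc * (u[qn] - u[qm]) / G.h;
        Qout += u[qn];
        ++nOutFluid;
      }
    if (nOutFluid > 0) {
      double corr = (Qin - Qout) / (double)nOutFluid;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          i64 qn = id3(nx, j, k, Su.NI, Su.NJ);
          if (Fu.type[qn] <= 1) u[qn] += corr;
        }
    }
  }

  // direct forcing: solid faces to zero, near-wall faces to the linear
  // no-slip interpolation along the inward normal
  void force(dvec& a, const FaceOps& O) {
    for (size_t m = 0; m < O.solid.size(); ++m) a[O.solid[m]] = 0.0;
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (size_t m = 0; m < O.forced.size(); ++m) {
        const i64* idx = &O.fsten_idx[54 * m];
        const double* wt = &O.fsten_w[54 * m];
        double s = 0.0;
        for (int t = 0; t < 54; ++t) s += wt[t] * a[idx[t]];
        a[O.forced[m]] = s;
      }
      for (size_t m = 0; m < O.ghost.size(); ++m) {
        const i64* idx = &O.gsten_idx[54 * m];
        const double* wt = &O.gsten_w[54 * m];
        double s = 0.0;
        for (int t = 0; t < 54; ++t) s += wt[t] * a[idx[t]];
        a[O.ghost[m]] = s;
      }
    }
  }
  void forceAll() {
    force(u, Ou);
    force(v, Ov);
    if (G.nz > 1) force(w, Ow);
  }

  // periodic-x runs: drive the flow so the sectional bulk velocity tracks
  // the waveform (equivalent to a uniform time-dependent pressure gradient)
  void bulkForce(double t) {
    if (!G.px) return;
    double Ub = waveform(t);
    for (int pass = 0; pass < 2; ++pass) {
      double flux = 0.0;
      for (int k = 0; k < G.nz; ++k)
        for (int j = 0; j < G.ny; ++j)
          for (int i = 0; i < G.nx; ++i) {
            i64 q = id3(i, j, k, Su.NI, Su.NJ);
            if (Fu.type[q] <= 1) flux += u[q];
          }
      double bulk = flux * G.h * G.h / ((double)G.nx * Asec);
      double du = Ub - bulk;
      if (pass == 1) {
        // exact residual fix on interior fluid faces only
        du *= ((double)G.nx * Asec) / ((double)nFluidU * G.h * G.h);
        for (i64 q = 0; q < (i64)Fu.type.size(); ++q)
          if (Fu.type[q] == 0) u[q] += du;
      } else {
        for (i64 q = 0; q < (i64)Fu.type.size(); ++q)
          if (Fu.type[q] <= 1) u[q] += du;
        forceAll();
      }
    }
    // keep mirrored face consistent
    for (int k = 0; k < G.nz; ++k)
      for (int j = 0; j < G.ny; ++j)
        u[id3(G.nx, j, k, Su.NI, Su.NJ)] = u[id3(0, j, k, Su.NI, Su.NJ)];
  }

  // -- RHS: advection (conservative central) + diffusion + old pressure ---
  void rhs() {
    int nx = G.nx, ny = G.ny, nz = G.nz;
    double h = G.h, ih = 1.0 / h, ih2 = ih * ih;
    bool twoD = (nz == 1);
    // u component
    int i0 = G.px ? 0 : 1, i1 = G.px ? nx - 1 : nx - 1;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = i0; i <= i1; ++i) {
          int im = i - 1, ip = i + 1;
          if (G.px) { im = (i + nx - 1) % nx; ip = (i + 1) % nx; }
          int km = G.pz ? (k + nz - 1) % nz : k - 1;
          int kp = G.pz ? (k + 1) % nz : k + 1;
          i64 q = id3(i, j, k, Su.NI, Su.NJ);
          double uc = u[q];
          double uE = u[id3(ip, j, k, Su.NI, Su.NJ)];
          double uW = u[id3(im, j, k, Su.NI, Su.NJ)];
          double uN = (j < ny-1) ? u[id3(i, j+1, k, Su.NI, Su.NJ)] : -uc;
          double uS = (j > 0)    ? u[id3(i, j-1, k, Su.NI, Su.NJ)] : -uc;
          double uT = twoD ? uc : ((G.pz || k < nz-1) ?
                      u[id3(i, j, kp, Su.NI, Su.NJ)] : -uc);
          double uB = twoD ? uc : ((G.pz || k > 0) ?
                      u[id3(i, j, km, Su.NI, Su.NJ)] : -uc);
          // transverse velocities straddling the u face (cells i-1 and i)
          int ic = i % nx, icm = (i - 1 + nx) % nx;
          if (!G.px) { ic = std::min(i, nx - 1); icm = i - 1; }
          double vS2 = 0.5*(v[id3(icm, j, k, Sv.NI, Sv.NJ)] +
                            v[id3(ic,  j, k, Sv.NI, Sv.NJ)]);
          double vN2 = 0.5*(v[id3(icm, j+1, k, Sv.NI, Sv.NJ)] +
                            v[id3(ic,  j+1, k, Sv.NI, Sv.NJ)]);
          double wB2 = twoD ? 0.0 : 0.5*(w[id3(icm, j, k, Sw.NI, Sw.NJ)] +
                                         w[id3(ic,  j, k, Sw.NI, Sw.NJ)]);
          double wT2 = twoD ? 0.0 : 0.5*(w[id3(icm, j, k+1, Sw.NI, Sw.NJ)] +
                                         w[id3(ic,  j, k+1, Sw.NI, Sw.NJ)]);
          double uuE = 0.25*(uc+uE)*(uc+uE), uuW = 0.25*(uc+uW)*(uc+uW);
          double adv = (uuE - uuW) * ih
                     + (0.5*(uc+uN)*vN2 - 0.5*(uc+uS)*vS2) * ih
                     + (twoD ? 0.0 :
                        (0.5*(uc+uT)*wT2 - 0.5*(uc+uB)*wB2) * ih);
          double lap = (uE + uW + uN + uS - 4.0*uc) * ih2
                     + (twoD ? 0.0 : (uT + uB - 2.0*uc) * ih2);
          double dpdx = (p[id3(ic, j, k, Sp.NI, Sp.NJ)] -
                         p[id3(icm, j, k, Sp.NI, Sp.NJ)]) * ih;
          ru[q] = -adv + nu * lap - dpdx / rho;
        }
    // v component
    for (int k = 0; k < nz; ++k)
      for (int j = 1; j <= ny - 1; ++j)
        for (int i = 0; i < nx; ++i) {
          int km = G.pz ? (k + nz - 1) % nz : k - 1;
          int kp = G.pz ? (k + 1) % nz : k + 1;
          i64 q = id3(i, j, k, Sv.NI, Sv.NJ);
          double vc = v[q];
          double vN = v[id3(i, j+1, k, Sv.NI, Sv.NJ)];
          double vS = v[id3(i, j-1, k, Sv.NI, Sv.NJ)];
          double vE, vW;
          if (G.px) {
            vE = v[id3((i+1)%nx, j, k, Sv.NI, Sv.NJ)];
            vW = v[id3((i+nx-1)%nx, j, k, Sv.NI, Sv.NJ)];
          } else {
            vE = (i < nx-1) ? v[id3(i+1, j, k, Sv.NI, Sv.NJ)] : vc;  // outlet
            vW = (i > 0)    ? v[id3(i-1, j, k, Sv.NI, Sv.NJ)] : -vc; // inlet
          }
          double vT = twoD ? vc : ((G.pz || k < nz-1) ?
                      v[id3(i, j, kp, Sv.NI, Sv.NJ)] : -vc);
          double vB = twoD ? vc : ((G.pz || k > 0) ?
                      v[id3(i, j, km, Sv.NI, Sv.NJ)] : -vc);
          int ipu = G.px ? (i + 1) % (nx) : i + 1;
          double uW2 = 0.5*(u[id3(i, j-1, k, Su.NI, Su.NJ)] +
                            u[id3(i, j, k, Su.NI, Su.NJ)]);
          double uE2 = 0.5*(u[id3(ipu, j-1, k, Su.NI, Su.NJ)] +
                            u[id3(ipu, j, k, Su.NI, Su.NJ)]);
          double wB2 = twoD ? 0.0 : 0.5*(w[id3(i, j-1, k, Sw.NI, Sw.NJ)] +
                                         w[id3(i, j, k, Sw.NI, Sw.NJ)]);
          double wT2 = twoD ? 0.0 : 0.5*(w[id3(i, j-1, k+1, Sw.NI, Sw.NJ)] +
                                         w[id3(i, j, k+1, Sw.NI, Sw.NJ)]);
          double ih_ = ih;
          double adv = (uE2*0.5*(vc+vE) - uW2*0.5*(vc+vW)) * ih_
                     + (0.25*(vc+vN)*(vc+vN) - 0.25*(vc+vS)*(vc+vS)) * ih_
                     + (twoD ? 0.0 :
                        (0.5*(vc+vT)*wT2 - 0.5*(vc+vB)*wB2) * ih_);
          double lap = (vE + vW + vN + vS - 4.0*vc) * ih2
                     + (twoD ? 0.0 : (vT + vB - 2.0*vc) * ih2);
          double dpdy = (p[id3(i, j, k, Sp.NI, Sp.NJ)] -
                         p[id3(i, j-1, k, Sp.NI, Sp.NJ)]) * ih;
          rv[q] = -adv + nu * lap - dpdy / rho;
        }
    // w component (3D only)
    if (!twoD) {
      int kk0 = G.pz ? 0 : 1, kk1 = G.pz ? nz - 1 : nz - 1;
      for (int k = kk0; k <= kk1; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int km = G.pz ? (k + nz - 1) % nz : k - 1;
            int kp = G.pz ? (k + 1) % nz : k + 1;
            i64 q = id3(i, j, k, Sw.NI, Sw.NJ);
            double wc = w[q];
            double wT = w[id3(i, j, kp, Sw.NI, Sw.NJ)];
            double wB = w[id3(i, j, km, Sw.NI, Sw.NJ)];
            double wN = (j < ny-1) ? w[id3(i, j+1, k, Sw.NI, Sw.NJ)] : -wc;
            double wS = (j > 0)    ? w[id3(i, j-1, k, Sw.NI, Sw.NJ)] : -wc;
            double wE, wW;
            if (G.px) {
              wE = w[id3((i+1)%nx, j, k, Sw.NI, Sw.NJ)];
              wW = w[id3((i+nx-1)%nx, j, k, Sw.NI, Sw.NJ)];
            } else {
              wE = (i < nx-1) ? w[id3(i+1, j, k, Sw.NI, Sw.NJ)] : wc;
              wW = (i > 0)    ? w[id3(i-1, j, k, Sw.NI, Sw.NJ)] : -wc;
            }
            int ipu = G.px ? (i + 1) % nx : i + 1;
            int kc = k % nz, kcm = (k - 1 + nz) % nz;
            if (!G.pz) { kc = std::min(k, nz - 1); kcm = k - 1; }
            double uW2 = 0.5*(u[id3(i, j, kcm, Su.NI, Su.NJ)] +
                              u[id3(i, j, kc, Su.NI, Su.NJ)]);
            double uE2 = 0.5*(u[id3(ipu, j, kcm, Su.NI, Su.NJ)] +
                              u[id3(ipu, j, kc, Su.NI, Su.NJ)]);
            double vS2 = 0.5*(v[id3(i, j, kcm, Sv.NI, Sv.NJ)] +
                              v[id3(i, j, kc, Sv.NI, Sv.NJ)]);
            double vN2 = 0.5*(v[id3(i, j+1, kcm, Sv.NI, Sv.NJ)] +
                              v[id3(i, j+1, kc, Sv.NI, Sv.NJ)]);
            double adv = (uE2*0.5*(wc+wE) - uW2*0.5*(wc+wW)) * ih
                       + (vN2*0.5*(wc+wN) - vS2*0.5*(wc+wS)) * ih
                       + (0.25*(wc+wT)*(wc+wT) - 0.25*(wc+wB)*(wc+wB)) * ih;
            double lap = (wE + wW + wN + wS + wT + wB - 6.0*wc) * ih2;
            double dpdz = (p[id3(i, j, kc, Sp.NI, Sp.NJ)] -
                           p[id3(i, j, kcm, Sp.NI, Sp.NJ)]) * ih;
            rw[q] = -adv + nu * lap - dpdz / rho;
          }
    }
  }

  // -- Poisson: L q = h^2 div(u), masked consistently with divergence() --
  // a cell-face connection is open iff the face is corrected by the
  // projection (interior to the box) AND carries fluid (type <= 1)
  bool openUf(int i, int j, int k) {
    if (!G.px && (i == 0 || i == G.nx)) return false;
    return Fu.type[id3(i, j, k, Su.NI, Su.NJ)] <= 1;
  }
  bool openVf(int i, int j, int k) {
    if (j == 0 || j == G.ny) return false;
    return Fv.type[id3(i, j, k, Sv.NI, Sv.NJ)] <= 1;
  }
  bool openWf(int i, int j, int k) {
    if (!G.pz && (k == 0 || k == G.nz)) return false;
    return Fw.type[id3(i, j, k, Sw.NI, Sw.NJ)] <= 1;
  }
  void applyL(const dvec& x, dvec& out) {
    int nx = G.nx, ny = G.ny, nz = G.nz;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          i64 q = id3(i, j, k, Sp.NI, Sp.NJ);
          double xc = x[q], acc = 0.0;
          int nnb = 0;
          if (openUf(i + 1, j, k)) {
            acc += x[id3(G.px ? (i+1)%nx : i+1, j, k, Sp.NI, Sp.NJ)]; ++nnb;
          }
          if (openUf(i, j, k)) {
            acc += x[id3(G.px ? (i+nx-1)%nx : i-1, j, k, Sp.NI, Sp.NJ)]; ++nnb;
          }
          if (openVf(i, j + 1, k)) { acc += x[id3(i, j+1, k, Sp.NI, Sp.NJ)]; ++nnb; }
          if (openVf(i, j, k))     { acc += x[id3(i, j-1, k, Sp.NI, Sp.NJ)]; ++nnb; }
          if (nz > 1) {
            if (openWf(i, j, k + 1)) {
              acc += x[id3(i, j, G.pz ? (k+1)%nz : k+1, Sp.NI, Sp.NJ)]; ++nnb;
            }
            if (openWf(i, j, k)) {
              acc += x[id3(i, j, G.pz ? (k+nz-1)%nz : k-1, Sp.NI, Sp.NJ)]; ++nnb;
            }
          }
          out[q] = acc - (double)nnb * xc;
        }
  }

  // divergence for the projection: ghost-extension faces (outside the
  // wall) are masked to zero so solid cells stay quiet and the pressure
  // responds to the fluid network only
  double divergence(int i, int j, int k) {
    auto um = [&](int ii, int jj, int kk) {
      i64 q = id3(ii, jj, kk, Su.NI, Su.NJ);
      return Fu.type[q] >= 2 ? 0.0 : u[q];
    };
    auto vm = [&](int ii, int jj, int kk) {
      i64 q = id3(ii, jj, kk, Sv.NI, Sv.NJ);
      return Fv.type[q] >= 2 ? 0.0 : v[q];
    };
    double d = um(i+1, j, k) - um(i, j, k) + vm(i, j+1, k) - vm(i, j, k);
    if (G.nz > 1) {  // w(nz) is mirrored to w(0) in periodic-z runs
      auto wm = [&](int ii, int jj, int kk) {
        i64 q = id3(ii, jj, kk, Sw.NI, Sw.NJ);
        return Fw.type[q] >= 2 ? 0.0 : w[q];
      };
      d += wm(i, j, k+1) - wm(i, j, k);
    }
    return d / G.h;
  }

  void project() {
    int nx = G.nx, ny = G.ny, nz = G.nz;
    i64 nc = (i64)nx * ny * nz;
    double ih = 1.0 / G.h;
    // rhs (note sign: we solve -L q = -h^2 div so the operator is SPD);
    // the compatibility mean is removed over cells connected to the
    // fluid network only (cells with no open face have b = 0 and stay
    // out of the solve)
    double bsum = 0.0;
    i64 nact = 0;
    std::vector<unsigned char> act(nc, 0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          i64 q = id3(i, j, k, Sp.NI, Sp.NJ);
          pois_b[q] = -G.h * G.h * divergence(i, j, k);
          bool a = openUf(i, j, k) || openUf(i + 1, j, k) ||
                   openVf(i, j, k) || openVf(i, j + 1, k);
          if (nz > 1) a = a || openWf(i, j, k) || openWf(i, j, k + 1);
          act[q] = a ? 1 : 0;
          if (a) { bsum += pois_b[q]; ++nact; }
        }
    if (nact > 0) bsum /= (double)nact;
    for (i64 q = 0; q < nc; ++q)
      pois_b[q] = act[q] ? pois_b[q] - bsum : 0.0;
    // CG, warm start from previous correction
    applyL(pois_x, pois_q);
    double rr = 0.0;
    for (i64 q = 0; q < nc; ++q) {
      pois_r[q] = pois_b[q] + pois_q[q];  // r = b - (-L)x = b + Lx
      pois_d[q] = pois_r[q];
      rr += pois_r[q] * pois_r[q];
    }
    double bnorm = 0.0;
    for (i64 q = 0; q < nc; ++q) bnorm += pois_b[q] * pois_b[q];
    bnorm = std::sqrt(bnorm);
    double tol = std::max(cg_rtol * bnorm, 1e-300);
    int it = 0;
    while (std::sqrt(rr) > tol && it < cg_maxit) {
      applyL(pois_d, pois_q);
      double dq = 0.0;
      for (i64 q = 0; q < nc; ++q) dq += pois_d[q] * (-pois_q[q]);
      if (dq <= 0.0) break;  // singular direction exhausted
      double alpha = rr / dq;
      double rr2 = 0.0;
      for (i64 q = 0; q < nc; ++q) {
        pois_x[q] += alpha * pois_d[q];
        pois_r[q] += alpha * pois_q[q];  // r -= alpha*(-L d)
        rr2 += pois_r[q] * pois_r[q];
      }
      double beta = rr2 / rr;
      rr = rr2;
      for (i64 q = 0; q < nc; ++q) pois_d[q] = pois_r[q] + beta * pois_d[q];
      ++it;
    }
    cg_iters_last = it;
    // velocity correction and pressure update.
    // We solved L q = h^2 div with q = dt * (pressure correction) / rho,
    // so u -= grad(q) removes the divergence and p accumulates rho*q/dt.
    int i0 = G.px ? 0 : 1;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = i0; i <= nx - 1; ++i) {
          if (!openUf(i, j, k)) continue;
          int icm = G.px ? (i + nx - 1) % nx : i - 1;
          u[id3(i, j, k, Su.NI, Su.NJ)] -=
            (pois_x[id3(i, j, k, Sp.NI, Sp.NJ)] -
             pois_x[id3(icm, j, k, Sp.NI, Sp.NJ)]) * ih;
        }
    if (G.px)
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          u[id3(nx, j, k, Su.NI, Su.NJ)] = u[id3(0, j, k, Su.NI, Su.NJ)];
    for (int k = 0; k < nz; ++k)
      for (int j = 1; j <= ny - 1; ++j)
        for (int i = 0; i < nx; ++i) {
          if (!openVf(i, j, k)) continue;
          v[id3(i, j, k, Sv.NI, Sv.NJ)] -=
            (pois_x[id3(i, j, k, Sp.NI, Sp.NJ)] -
             pois_x[id3(i, j-1, k, Sp.NI, Sp.NJ)]) * ih;
        }
    if (nz > 1) {
      int k0 = G.pz ? 0 : 1;
      for (int k = k0; k <= nz - 1; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            if (!openWf(i, j, k)) continue;
            int kcm = G.pz ? (k + nz - 1) % nz : k - 1;
            w[id3(i, j, k, Sw.NI, Sw.NJ)] -=
              (pois_x[id3(i, j, k, Sp.NI, Sp.NJ)] -
               pois_x[id3(i, j, kcm, Sp.NI, Sp.NJ)]) * ih;
          }
      if (G.pz)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i)
            w[id3(i, j, nz, Sw.NI, Sw.NJ)] = w[id3(i, j, 0, Sw.NI, Sw.NJ)];
    }
    // accumulate pressure: p += rho * q / dt
    for (i64 q = 0; q < nc; ++q) p[q] += rho * pois_x[q] / dt;
    // max divergence over fluid cells
    double dmax = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (cellFluid[id3(i, j, k, Sp.NI, Sp.NJ)]) {
            double d = std::fabs(divergence(i, j, k));
            if (d > dmax) dmax = d;
          }
    div_max_last = dmax;
  }

  void rk3Step(double t) {
    const double A[3] = {0.0, -5.0/9.0, -153.0/128.0};
    const double B[3] = {1.0/3.0, 15.0/16.0, 8.0/15.0};
    const double Ct[3] = {1.0/3.0, 3.0/4.0, 1.0};
    std::fill(qu.begin(), qu.end(), 0.0);
    std::fill(qv.begin(), qv.end(), 0.0);
    std::fill(qw.begin(), qw.end(), 0.0);
    for (int s = 0; s < 3; ++s) {
      rhs();
      int i0 = G.px ? 0 : 1;
      for (int k = 0; k < G.nz; ++k)
        for (int j = 0; j < G.ny; ++j)
          for (int i = i0; i <= G.nx - 1; ++i) {
            i64 q = id3(i, j, k, Su.NI, Su.NJ);
            qu[q] = A[s] * qu[q] + dt * ru[q];
            u[q] += B[s] * qu[q];
          }
      for (int k = 0; k < G.nz; ++k)
        for (int j = 1; j <= G.ny - 1; ++j)
          for (int i = 0; i < G.nx; ++i) {
            i64 q = id3(i, j, k, Sv.NI, Sv.NJ);
            qv[q] = A[s] * qv[q] + dt * rv[q];
            v[q] += B[s] * qv[q];
          }
      if (G.nz > 1) {
        int k0 = G.pz ? 0 : 1;
        for (int k = k0; k <= G.nz - 1; ++k)
          for (int j = 0; j < G.ny; ++j)
            for (int i = 0; i < G.nx; ++i) {
              i64 q = id3(i, j, k, Sw.NI, Sw.NJ);
              qw[q] = A[s] * qw[q] + dt * rw[q];
              w[q] += B[s] * qw[q];
            }
      }
      double ts = t + Ct[s] * dt;
      applyBC(ts);
      forceAll();
      if (G.px) bulkForce(ts); else outletConvective(B[s] * dt, ts);
    }
    project();
  }
};

// ---------------------------------------------------------------------------
// scalar transport kernel: conservative first-order upwind fluxes over
// fluid cells; faces adjacent to solid cells carry no scalar flux.
// Returns (influx, outflux, clamped) through the inlet/outlet planes.
static void scalar_step(dvec& r, const Solver& S, double dt, double* influx,
                        double* outflux, double* clamped) {
  const Box& G = S.G;
  int nx = G.nx, ny = G.ny, nz = G.nz;
  double h = G.h, a = dt / h;
  dvec rn = r;
  double fin = 0.0, fout = 0.0, cl = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        i64 c = id3(i, j, k, S.Sp.NI, S.Sp.NJ);
        if (!S.cellFluid[c]) continue;
        double acc = 0.0;  // net outflow per face area
        // x faces (f = 0 west, f = 1 east); flux counted + in +x direction
        for (int f = 0; f < 2; ++f) {
          double uf = S.u[id3(i + f, j, k, S.Su.NI, S.Su.NJ)];
          int inb = f ? i + 1 : i - 1;
          if (!G.px && inb < 0) {
            // inlet plane: inflow carries the normalized value 1
            double flux = uf * ((uf > 0) ? 1.0 : r[c]);
            acc -= flux;
            fin += flux * h * h * dt;  // signed influx
            continue;
          }
          if (!G.px && inb >= nx) {
            // outlet plane: convective outflow, upwind from the interior
            double flux = uf * r[c];
            acc += flux;
            fout += flux * h * h * dt;  // signed outflux
            continue;
          }
          i64 cnb = id3(G.px ? ((inb % nx) + nx) % nx : inb, j, k,
                        S.Sp.NI, S.Sp.NJ);
          if (!S.cellFluid[cnb]) continue;  // no scalar flux into the wall
          double up = (uf > 0) ? (f ? r[c] : r[cnb]) : (f ? r[cnb] : r[c]);
          acc += (f ? 1.0 : -1.0) * uf * up;
        }
        // y faces
        for (int f = 0; f < 2; ++f) {
          int jn = f ? j + 1 : j - 1;
          if (jn < 0 || jn >= ny) continue;  // box wall is solid
          i64 cnb = id3(i, jn, k, S.Sp.NI, S.Sp.NJ);
          if (!S.cellFluid[cnb]) continue;
          double vf = S.v[id3(i, j + f, k, S.Sv.NI, S.Sv.NJ)];
          double up = (vf > 0) ? (f ? r[c] : r[cnb]) : (f ? r[cnb] : r[c]);
          double flux = vf * up;
          acc += (f ? flux : -flux);
        }
        // z faces
        if (nz > 1) {
          for (int f = 0; f < 2; ++f) {
            int kn = f ? k + 1 : k - 1;
            i64 cnb;
            if (G.pz) cnb = id3(i, j, ((kn % nz) + nz) % nz, S.Sp.NI, S.Sp.NJ);
            else if (kn < 0 || kn >= nz) continue;
            else cnb = id3(i, j, kn, S.Sp.NI, S.Sp.NJ);
            if (!S.cellFluid[cnb]) continue;
            double wf = S.w[id3(i, j, k + f, S.Sw.NI, S.Sw.NJ)];
            double up = (wf > 0) ? (f ? r[c] : r[cnb]) : (f ? r[cnb] : r[c]);
            double flux = wf * up;
            acc += (f ? flux : -flux);
          }
        }
        rn[c] = r[c] - a * acc;
        if (rn[c] < 0.0) { cl += -rn[c] * h * h * h; rn[c] = 0.0; }
      }
  r.swap(rn);
  *influx = fin; *outflux = fout; *clamped = cl;
}

// ---------------------------------------------------------------------------
// wall shear stress at sample points: one-sided second-order normal gradient
// of the tangential velocity using probes at 1h and 2h along the inward
// normal; u = 0 at the wall.
static void wall_wss(const Solver& S, const NumericMatrix& wp,
                     const NumericMatrix& wn, const std::vector<int>& valid,
                     dvec& wss) {
  int m = wp.nrow();
  double h = S.G.h;
  for (int q = 0; q < m; ++q) {
    if (!valid[q]) { wss[q] = NA_REAL; continue; }
    double n1 = wn(q,0), n2 = wn(q,1), n3 = wn(q,2);
    double t1[3], t2[3];
    for (int d = 0; d < 2; ++d) {
      double px = wp(q,0) + (d+1)*h*n1, py = wp(q,1) + (d+1)*h*n2,
             pz = wp(q,2) + (d+1)*h*n3;
      double uu = tri_sample_q(S.u, S.Su, S.G, px, py, pz);
      double vv = tri_sample_q(S.v, S.Sv, S.G, px, py, pz);
      double ww = (S.G.nz > 1) ? tri_sample_q(S.w, S.Sw, S.G, px, py, pz) : 0.0;
      double un = uu*n1 + vv*n2 + ww*n3;
      double* t = d ? t2 : t1;
      t[0] = uu - un*n1; t[1] = vv - un*n2; t[2] = ww - un*n3;
    }
    double gx = (4.0*t1[0] - t2[0]) / (2.0*h);
    double gy = (4.0*t1[1] - t2[1]) / (2.0*h);
    double gz = (4.0*t1[2] - t2[2]) / (2.0*h);
    wss[q] = S.mu * std::sqrt(gx*gx + gy*gy + gz*gz);
  }
}

// ---------------------------------------------------------------------------
static void init_solver(Solver& S, const List& cfg) {
  S.G.nx = as<int>(cfg["nx"]); S.G.ny = as<int>(cfg["ny"]);
  S.G.nz = as<int>(cfg["nz"]); S.G.h = as<double>(cfg["h"]);
  S.G.px = as<bool>(cfg["periodic_x"]);
  S.G.pz = as<bool>(cfg["periodic_z"]);
  int nx = S.G.nx, ny = S.G.ny, nz = S.G.nz;
  S.Su = {nx + 1, ny, nz, 0.0, 0.5, 0.5};
  S.Sv = {nx, ny + 1, nz, 0.5, 0.0, 0.5};
  S.Sw = {nx, ny, nz + 1, 0.5, 0.5, 0.0};
  S.Sp = {nx, ny, nz, 0.5, 0.5, 0.5};
  S.phi = as<dvec>(cfg["phi"]);
  S.rho = as<double>(cfg["rho_f"]); S.mu = as<double>(cfg["mu"]);
  S.nu = S.mu / S.rho;
  S.dt = as<double>(cfg["dt"]);
  NumericMatrix wf = cfg["waveform"];
  for (int m = 0; m < wf.nrow(); ++m) {
    S.wf_t.push_back(wf(m, 0)); S.wf_u.push_back(wf(m, 1));
  }
  S.wf_T = (wf.nrow() > 1) ? S.wf_t.back() : 1.0;
  S.cg_rtol = as<double>(cfg["cg_rtol"]);
  S.cg_maxit = as<int>(cfg["cg_maxit"]);
  S.uconv_min = as<double>(cfg["uconv_min"]);
  auto alloc = [](dvec& a, const Stag& St) {
    a.assign((i64)St.NI * St.NJ * St.NK, 0.0);
  };
  alloc(S.u, S.Su); alloc(S.v, S.Sv); alloc(S.w, S.Sw); alloc(S.p, S.Sp);
  alloc(S.qu, S.Su); alloc(S.qv, S.Sv); alloc(S.qw, S.Sw);
  alloc(S.ru, S.Su); alloc(S.rv, S.Sv); alloc(S.rw, S.Sw);
  alloc(S.pois_b, S.Sp); alloc(S.pois_x, S.Sp); alloc(S.pois_r, S.Sp);
  alloc(S.pois_d, S.Sp); alloc(S.pois_q, S.Sp);
  if (cfg.containsElementNamed("u0") && !Rf_isNull(cfg["u0"])) {
    S.u = as<dvec>(cfg["u0"]); S.v = as<dvec>(cfg["v0"]);
    S.w = as<dvec>(cfg["w0"]); S.p = as<dvec>(cfg["p0"]);
  }
  classify(S.phi, S.G, S.Su, S.Fu);
  classify(S.phi, S.G, S.Sv, S.Fv);
  classify(S.phi, S.G, S.Sw, S.Fw);
  // ghost faces on the inlet/outlet planes would leak uncounted flux
  // through the domain boundary: demote them to plain solid (zero)
  if (!S.G.px)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        i64 q0 = id3(0, j, k, S.Su.NI, S.Su.NJ);
        i64 qn = id3(nx, j, k, S.Su.NI, S.Su.NJ);
        if (S.Fu.type[q0] == 3) S.Fu.type[q0] = 2;
        if (S.Fu.type[qn] == 3) S.Fu.type[qn] = 2;
      }
  build_faceops(S.Fu, S.Su, S.G, S.Ou);
  build_faceops(S.Fv, S.Sv, S.G, S.Ov);
  build_faceops(S.Fw, S.Sw, S.G, S.Ow);
  S.cellFluid.assign((i64)nx * ny * nz, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double x = (i + 0.5) * S.G.h, y = (j + 0.5) * S.G.h,
               z = (k + 0.5) * S.G.h;
        if (phi_at(S.phi, S.G, x, y, z) < 0.0)
          S.cellFluid[id3(i, j, k, nx, ny)] = 1;
      }
  S.inletProf.assign((i64)ny * nz, 0.0);
  if (cfg.containsElementNamed("inlet_profile") &&
      !Rf_isNull(cfg["inlet_profile"]))
    S.inletProf = as<dvec>(cfg["inlet_profile"]);
  // section areas
  double ain = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      if (S.Fu.type[id3(0, j, k, S.Su.NI, S.Su.NJ)] <= 1)
        ain += S.G.h * S.G.h;
  S.Ain = ain;
  i64 nf = 0; double asec = 0.0;
  int imid = nx / 2;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      if (S.Fu.type[id3(imid, j, k, S.Su.NI, S.Su.NJ)] <= 1)
        asec += S.G.h * S.G.h;
  for (i64 q = 0; q < (i64)S.Fu.type.size(); ++q)
    if (S.Fu.type[q] == 0) ++nf;
  S.Asec = asec; S.nFluidU = nf;
  // exact lumen section area (from the contour geometry) supersedes the
  // stair-step face count for bulk-velocity enforcement
  if (cfg.containsElementNamed("section_area") &&
      !Rf_isNull(cfg["section_area"]))
    S.Asec = as<double>(cfg["section_area"]);
}

// adhesion rate law k_l(WSS): 0 above the threshold; at or below it either a
// linear ramp peaking at zero shear (law 0) or a constant step (law 1).
static inline double rate_k(double wss, double kmax, double th, int law) {
  if (wss > th) return 0.0;
  if (law == 1) return kmax;
  return kmax * (1.0 - wss / th);
}

// [[Rcpp::export]]
List cpp_run(List cfg) {
  Solver S;
  init_solver(S, cfg);
  int n_steps = as<int>(cfg["n_steps"]);
  double t = as<double>(cfg["t0"]);
  int record_stride = as<int>(cfg["record_stride"]);
  int record_start = as<int>(cfg["record_start"]);
  int ledger_start = as<int>(cfg["ledger_start"]);
  IntegerVector snapAt = cfg.containsElementNamed("snapshot_steps")
    ? as<IntegerVector>(cfg["snapshot_steps"]) : IntegerVector(0);
  NumericMatrix probes = cfg.containsElementNamed("probes") &&
    !Rf_isNull(cfg["probes"]) ? as<NumericMatrix>(cfg["probes"])
                              : NumericMatrix(0, 3);

  // wall samples
  NumericMatrix wpts(0, 3), wnrm(0, 3);
  bool haveWall = cfg.containsElementNamed("wall_points") &&
                  !Rf_isNull(cfg["wall_points"]);
  if (haveWall) {
    wpts = as<NumericMatrix>(cfg["wall_points"]);
    wnrm = as<NumericMatrix>(cfg["wall_normals"]);
  }
  int nwall = wpts.nrow();
  std::vector<int> wvalid(nwall, 1);
  for (int q = 0; q < nwall; ++q) {
    for (int d = 1; d <= 2; ++d) {
      double px = wpts(q,0) + d*S.G.h*wnrm(q,0);
      double py = wpts(q,1) + d*S.G.h*wnrm(q,1);
      double pz = wpts(q,2) + d*S.G.h*wnrm(q,2);
      if (phi_at(S.phi, S.G, px, py, pz) >= 0.0) wvalid[q] = 0;
    }
  }

  // species
  List speciesList = cfg.containsElementNamed("species") &&
    !Rf_isNull(cfg["species"]) ? as<List>(cfg["species"]) : List(0);
  int nsp = speciesList.size();
  std::vector<double> sp_kmax(nsp), sp_th(nsp);
  std::vector<int> sp_law(nsp), sp_tracked(nsp);
  std::vector<dvec> rho_l(nsp);
  i64 ncell = (i64)S.G.nx * S.G.ny * S.G.nz;
  for (int s = 0; s < nsp; ++s) {
    List sp = speciesList[s];
    sp_kmax[s] = as<double>(sp["k_max"]);
    sp_th[s] = as<double>(sp["wss_th"]);
    sp_law[s] = as<int>(sp["law"]);
    sp_tracked[s] = as<int>(sp["tracked"]);
    rho_l[s].assign(ncell, 1.0);
    for (i64 c = 0; c < ncell; ++c)
      if (!S.cellFluid[c]) rho_l[s][c] = 0.0;
  }

  // wall-adjacent fluid cells and their governing wall sample
  std::vector<i64> wcell;
  std::vector<int> wcellSample;
  if (haveWall && nsp > 0) {
    int nx = S.G.nx, ny = S.G.ny, nz = S.G.nz;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          i64 c = id3(i, j, k, nx, ny);
          if (!S.cellFluid[c]) continue;
          bool nearWall = false;
          const int di[6] = {1,-1,0,0,0,0}, dj[6] = {0,0,1,-1,0,0},
                    dk[6] = {0,0,0,0,1,-1};
          for (int f = 0; f < 6; ++f) {
            int in = i + di[f], jn = j + dj[f], kn = k + dk[f];
            if (S.G.px) in = ((in % nx) + nx) % nx;
            else if (in < 0 || in >= nx) continue;
            if (jn < 0 || jn >= ny) { nearWall = true; break; }
            if (nz > 1) {
              if (S.G.pz) kn = ((kn % nz) + nz) % nz;
              else if (kn < 0 || kn >= nz) { nearWall = true; break; }
            } else kn = 0;
            if (!S.cellFluid[id3(in, jn, kn, nx, ny)]) { nearWall = true; break; }
          }
          if (!nearWall) continue;
          double x = (i + .5)*S.G.h, y = (j + .5)*S.G.h, z = (k + .5)*S.G.h;
          double best = 1e300; int bq = -1;
          for (int q = 0; q < nwall; ++q) {
            double dx = x - wpts(q,0), dy = y - wpts(q,1), dz = z - wpts(q,2);
            double d2 = dx*dx + dy*dy + dz*dz;
            if (d2 < best) { best = d2; bq = q; }
          }
          if (bq >= 0) { wcell.push_back(c); wcellSample.push_back(bq); }
        }
  }

  // output buffers
  int nrec = 0;
  for (int st = 1; st <= n_steps; ++st)
    if (st >= record_start && ((st - record_start) % record_stride == 0)) ++nrec;
  NumericMatrix wssRec(nwall > 0 ? nwall : 1, nwall > 0 ? nrec : 1);
  NumericVector recTimes(nrec);
  NumericMatrix probeRec(probes.nrow() * 3 > 0 ? probes.nrow() * 3 : 1,
                         probes.nrow() > 0 ? nrec : 1);
  dvec wssNow(nwall, 0.0), wssSum(nwall, 0.0);
  i64 wssCount = 0;
  NumericMatrix logm(n_steps, 7);  // t, maxdiv, Qin, Qout, Ub, cgit, umax
  std::vector<dvec> ledger(nsp, dvec(std::max(nwall, 1), 0.0));
  // scalar balance accumulators (from ledger_start on)
  std::vector<double> sc_in(nsp, 0.0), sc_out(nsp, 0.0), sc_sink(nsp, 0.0),
                      sc_clamp(nsp, 0.0), sc_store0(nsp, NA_REAL);
  List snaps;
  double h3 = S.G.h * S.G.h * S.G.h;
  bool blowup = false; int blowupStep = -1;

  for (int st = 1; st <= n_steps; ++st) {
    S.rk3Step(t);
    t += S.dt;
    // instantaneous WSS (needed for the adhesion sink each step)
    if (nwall > 0) {
      wall_wss(S, wpts, wnrm, wvalid, wssNow);
      if (st >= ledger_start) {
        for (int q = 0; q < nwall; ++q)
          if (wvalid[q]) wssSum[q] += wssNow[q];
        ++wssCount;
      }
    }
    // scalar transport + sink
    for (int s = 0; s < nsp; ++s) {
      bool accrue = (st >= ledger_start);
      if (sp_tracked[s]) {
        double fin, fout, cl;
        scalar_step(rho_l[s], S, S.dt, &fin, &fout, &cl);
        if (accrue) {
          if (!R_finite(sc_store0[s])) {
            sc_store0[s] = 0.0;
            for (i64 c = 0; c < ncell; ++c)
              if (S.cellFluid[c]) sc_store0[s] += rho_l[s][c] * h3;
            // store0 measured after this step's advection; include this
            // step's fluxes from the next step on instead
            sc_in[s] = 0.0; sc_out[s] = 0.0; sc_clamp[s] = 0.0;
          } else {
            sc_in[s] += fin; sc_out[s] += fout; sc_clamp[s] += cl;
          }
        }
        for (size_t m = 0; m < wcell.size(); ++m) {
          int q = wcellSample[m];
          if (!wvalid[q]) continue;
          double kk = rate_k(wssNow[q], sp_kmax[s], sp_th[s], sp_law[s]);
          if (kk <= 0.0) continue;
          i64 c = wcell[m];
          double dec = std::exp(-kk * S.dt);
          double removed = rho_l[s][c] * (1.0 - dec) * h3;
          rho_l[s][c] *= dec;
          if (accrue) {
            ledger[s][q] += removed;
            if (R_finite(sc_store0[s])) sc_sink[s] += removed;
          }
        }
      } else if (accrue) {
        // uniform-concentration mode: rho = 1 everywhere, field untouched
        for (size_t m = 0; m < wcell.size(); ++m) {
          int q = wcellSample[m];
          if (!wvalid[q]) continue;
          double kk = rate_k(wssNow[q], sp_kmax[s], sp_th[s], sp_law[s]);
          if (kk > 0.0) ledger[s][q] += kk * 1.0 * S.dt * h3;
        }
      }
    }
    // logs
    double qin = 0.0, qout = 0.0, umax = 0.0;
    if (!S.G.px) {
      for (int k = 0; k < S.G.nz; ++k)
        for (int j = 0; j < S.G.ny; ++j) {
          qin += S.u[id3(0, j, k, S.Su.NI, S.Su.NJ)] * S.G.h * S.G.h;
          qout += S.u[id3(S.G.nx, j, k, S.Su.NI, S.Su.NJ)] * S.G.h * S.G.h;
        }
    }
    for (i64 q = 0; q < (i64)S.u.size(); ++q)
      if (std::fabs(S.u[q]) > umax) umax = std::fabs(S.u[q]);
    logm(st-1, 0) = t; logm(st-1, 1) = S.div_max_last;
    logm(st-1, 2) = qin; logm(st-1, 3) = qout;
    logm(st-1, 4) = S.waveform(t); logm(st-1, 5) = S.cg_iters_last;
    logm(st-1, 6) = umax;
    if (!std::isfinite(umax) || umax > 1e6) { blowup = true; blowupStep = st; break; }
    // recording
    if (st >= record_start && ((st - record_start) % record_stride == 0)) {
      int rcol = (st - record_start) / record_stride;
      if (rcol < nrec) {
        recTimes[rcol] = t;
        for (int q = 0; q < nwall; ++q) wssRec(q, rcol) = wssNow[q];
        for (int m = 0; m < probes.nrow(); ++m) {
          probeRec(3*m+0, rcol) = tri_sample(S.u, S.Su, S.G, probes(m,0), probes(m,1), probes(m,2));
          probeRec(3*m+1, rcol) = tri_sample(S.v, S.Sv, S.G, probes(m,0), probes(m,1), probes(m,2));
          probeRec(3*m+2, rcol) = (S.G.nz > 1) ? tri_sample(S.w, S.Sw, S.G, probes(m,0), probes(m,1), probes(m,2)) : 0.0;
        }
      }
    }
    for (int m = 0; m < snapAt.size(); ++m)
      if (snapAt[m] == st)
        snaps.push_back(List::create(_["step"] = st, _["t"] = t,
                                     _["u"] = NumericVector(S.u.begin(), S.u.end()),
                                     _["v"] = NumericVector(S.v.begin(), S.v.end()),
                                     _["w"] = NumericVector(S.w.begin(), S.w.end())));
    if (st % 200 == 0) Rcpp::checkUserInterrupt();
  }

  // final scalar storage
  NumericVector storeEnd(nsp), storeBeg(nsp), inN(nsp), outN(nsp),
                sinkN(nsp), clampN(nsp);
  for (int s = 0; s < nsp; ++s) {
    double tot = 0.0;
    for (i64 c = 0; c < ncell; ++c) if (S.cellFluid[c]) tot += rho_l[s][c] * h3;
    storeEnd[s] = tot; storeBeg[s] = sc_store0[s];
    inN[s] = sc_in[s]; outN[s] = sc_out[s]; sinkN[s] = sc_sink[s];
    clampN[s] = sc_clamp[s];
  }
  List ledgerOut(nsp), rhoOut(nsp);
  for (int s = 0; s < nsp; ++s) {
    ledgerOut[s] = NumericVector(ledger[s].begin(), ledger[s].end());
    rhoOut[s] = NumericVector(rho_l[s].begin(), rho_l[s].end());
  }
  NumericVector wssMean(nwall);
  for (int q = 0; q < nwall; ++q)
    wssMean[q] = wssCount > 0 ? wssSum[q] / (double)wssCount : NA_REAL;

  return List::create(
    _["u"] = NumericVector(S.u.begin(), S.u.end()),
    _["v"] = NumericVector(S.v.begin(), S.v.end()),
    _["w"] = NumericVector(S.w.begin(), S.w.end()),
    _["p"] = NumericVector(S.p.begin(), S.p.end()),
    _["t"] = t,
    _["log"] = logm,
    _["wss"] = wssRec,
    _["wss_mean"] = wssMean,
    _["wss_valid"] = IntegerVector(wvalid.begin(), wvalid.end()),
    _["rec_times"] = recTimes,
    _["probe_vel"] = probeRec,
    _["ledger"] = ledgerOut,
    _["rho"] = rhoOut,
    _["scalar_balance"] = List::create(
      _["influx"] = inN, _["outflux"] = outN, _["sink"] = sinkN,
      _["clamped"] = clampN, _["storage_begin"] = storeBeg,
      _["storage_end"] = storeEnd),
    _["snapshots"] = snaps,
    _["cell_fluid"] = IntegerVector(S.cellFluid.begin(), S.cellFluid.end()),
    _["blowup"] = blowup,
    _["blowup_step"] = blowupStep,
    _["inlet_area"] = S.Ain);
}

// ---------------------------------------------------------------------------
// standalone helpers exposed to the R layer

// [[Rcpp::export]]
NumericMatrix cpp_sample_velocity(NumericVector u, NumericVector v,
                                  NumericVector w, int nx, int ny, int nz,
                                  double h, bool periodic_x, bool periodic_z,
                                  NumericMatrix pts) {
  Box G; G.nx = nx; G.ny = ny; G.nz = nz; G.h = h;
  G.px = periodic_x; G.pz = periodic_z;
  Stag Su = {nx + 1, ny, nz, 0.0, 0.5, 0.5};
  Stag Sv = {nx, ny + 1, nz, 0.5, 0.0, 0.5};
  Stag Sw = {nx, ny, nz + 1, 0.5, 0.5, 0.0};
  dvec uu = as<dvec>(u), vv = as<dvec>(v), ww = as<dvec>(w);
  NumericMatrix out(pts.nrow(), 3);
  for (int m = 0; m < pts.nrow(); ++m) {
    out(m, 0) = tri_sample(uu, Su, G, pts(m,0), pts(m,1), pts(m,2));
    out(m, 1) = tri_sample(vv, Sv, G, pts(m,0), pts(m,1), pts(m,2));
    out(m, 2) = (nz > 1) ? tri_sample(ww, Sw, G, pts(m,0), pts(m,1), pts(m,2)) : 0.0;
  }
  return out;
}

// instantaneous wall shear stress at sample points for a single stored
// velocity field (same probe scheme as the coupled run loop)
// [[Rcpp::export]]
List cpp_wall_wss(NumericVector u, NumericVector v, NumericVector w,
                  NumericVector phi, int nx, int ny, int nz, double h,
                  bool periodic_x, bool periodic_z, double mu,
                  NumericMatrix points, NumericMatrix normals) {
  Solver S;
  S.G.nx = nx; S.G.ny = ny; S.G.nz = nz; S.G.h = h;
  S.G.px = periodic_x; S.G.pz = periodic_z;
  S.Su = {nx + 1, ny, nz, 0.0, 0.5, 0.5};
  S.Sv = {nx, ny + 1, nz, 0.5, 0.0, 0.5};
  S.Sw = {nx, ny, nz + 1, 0.5, 0.5, 0.0};
  S.u = as<dvec>(u); S.v = as<dvec>(v); S.w = as<dvec>(w);
  S.phi = as<dvec>(phi);
  S.mu = mu;
  int m = points.nrow();
  std::vector<int> valid(m, 1);
  for (int q = 0; q < m; ++q)
    for (int d = 1; d <= 2; ++d) {
      double px = points(q,0) + d*h*normals(q,0);
      double py = points(q,1) + d*h*normals(q,1);
      double pz = points(q,2) + d*h*normals(q,2);
      if (phi_at(S.phi, S.G, px, py, pz) >= 0.0) valid[q] = 0;
    }
  dvec wss(m, 0.0);
  wall_wss(S, points, normals, valid, wss);
  return List::create(_["wss"] = NumericVector(wss.begin(), wss.end()),
                      _["valid"] = IntegerVector(valid.begin(), valid.end()));
}

// one explicit upwind advection step for a scalar on the staggered grid;
// used by the standalone transport operation (same kernel as the coupled
// run).  Returns list(rho, influx, outflux, clamped).
// [[Rcpp::export]]
List cpp_scalar_step(NumericVector rho, NumericVector u, NumericVector v,
                     NumericVector w, NumericVector phi, int nx, int ny,
                     int nz, double h, bool periodic_x, bool periodic_z,
                     double dt) {
  Solver S;
  S.G.nx = nx; S.G.ny = ny; S.G.nz = nz; S.G.h = h;
  S.G.px = periodic_x; S.G.pz = periodic_z;
  S.Su = {nx + 1, ny, nz, 0.0, 0.5, 0.5};
  S.Sv = {nx, ny + 1, nz, 0.5, 0.0, 0.5};
  S.Sw = {nx, ny, nz + 1, 0.5, 0.5, 0.0};
  S.Sp = {nx, ny, nz, 0.5, 0.5, 0.5};
  S.u = as<dvec>(u); S.v = as<dvec>(v); S.w = as<dvec>(w);
  S.phi = as<dvec>(phi);
  S.cellFluid.assign((i64)nx * ny * nz, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (phi_at(S.phi, S.G, (i+.5)*h, (j+.5)*h, (k+.5)*h) < 0.0)
          S.cellFluid[id3(i, j, k, nx, ny)] = 1;
  dvec r = as<dvec>(rho);
  double fin, fout, cl;
  scalar_step(r, S, dt, &fin, &fout, &cl);
  return List::create(_["rho"] = NumericVector(r.begin(), r.end()),
                      _["influx"] = fin, _["outflux"] = fout,
                      _["clamped"] = cl);
}

// signed distance (radial approximation, exact for circular cross-sections)
// to a tube surface given a finely resampled centerline with
// parallel-transport frames and a radius table over (s, theta).
// [[Rcpp::export]]
NumericVector cpp_tube_signed_distance(NumericMatrix pts, NumericMatrix cl,
                                       NumericMatrix e1, NumericMatrix e2,
                                       NumericVector s_cl,
                                       NumericVector s_tab,
                                       NumericMatrix rad_tab) {
  int np = pts.nrow(), nc = cl.nrow();
  int nsr = rad_tab.nrow(), M = rad_tab.ncol();
  NumericVector out(np);
  for (int m = 0; m < np; ++m) {
    double x = pts(m,0), y = pts(m,1), z = pts(m,2);
    double best = 1e300; int bi = 0;
    for (int c = 0; c < nc; ++c) {
      double dx = x - cl(c,0), dy = y - cl(c,1), dz = z - cl(c,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bi = c; }
    }
    double dx = x - cl(bi,0), dy = y - cl(bi,1), dz = z - cl(bi,2);
    double a = dx*e1(bi,0) + dy*e1(bi,1) + dz*e1(bi,2);
    double b = dx*e2(bi,0) + dy*e2(bi,1) + dz*e2(bi,2);
    double rr = std::sqrt(a*a + b*b);
    double th = std::atan2(b, a);
    if (th < 0) th += 2.0 * M_PI;
    // radius at (s(bi), th): bilinear in the table, periodic in theta
    double sq = s_cl[bi];
    int i1 = 0;
    while (i1 < nsr - 2 && s_tab[i1 + 1] < sq) ++i1;
    double fs = (sq - s_tab[i1]) / (s_tab[i1+1] - s_tab[i1]);
    fs = std::min(1.0, std::max(0.0, fs));
    double dth = 2.0 * M_PI / M;
    int t1 = (int)std::floor(th / dth);
    double ft = th / dth - t1;
    t1 = ((t1 % M) + M) % M;
    int t2 = (t1 + 1) % M;
    double r1 = rad_tab(i1, t1) * (1-ft) + rad_tab(i1, t2) * ft;
    double r2 = rad_tab(i1+1, t1) * (1-ft) + rad_tab(i1+1, t2) * ft;
    double rsurf = r1 * (1-fs) + r2 * fs;
    out[m] = rr - rsurf;
  }
  return out;
}
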