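// Weakly-compressible axisymmetric Navier-Stokes core.
//
// Conservative finite differences on a cell-centered (r, z) grid with ghost
// layers. Advective + pressure fluxes use global Lax-Friedrichs splitting
// with linear upwind-biased flux interpolation (order 7/5/3 in the interior,
// reduced to 3 then 1 where a stencil would cross a wall). Viscous stresses
// are evaluated at cell faces (2nd order) with spatially varying viscosity.
// The axis is handled by parity ghost rows, walls by a staircase mask with
// impermeable faces (advective flux zero, pressure retained) and no-slip
// ghost extrapolation. Time integration is SSP-RK3 with an acoustic+viscous
// CFL limit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double C1[1] = {1.0};
static const double C3[3] = {-1.0 / 6.0, 5.0 / 6.0, 2.0 / 6.0};
static const double C5[5] = {2.0 / 60.0, -13.0 / 60.0, 47.0 / 60.0,
                             27.0 / 60.0, -3.0 / 60.0};
static const double C7[7] = {-3.0 / 420.0, 25.0 / 420.0, -101.0 / 420.0,
                             319.0 / 420.0, 214.0 / 420.0, -38.0 / 420.0,
                             4.0 / 420.0};

struct SolidFill {
  int idx;        // linear index of the layer-1 solid cell
  int ndir;
  int off[4];     // offsets toward the fluid neighbor(s)
  int has2[4];    // 1 if the second cell further along off is also fluid
};

struct Ctx {
  int nr, nz, g, NR, NZ;
  double dr, dz, zmin;
  // EOS
  double rho0, c0, p0, gam;
  // rheology: 0 newtonian, 1 carreau-yasuda, 2 casson
  int rheol;
  double mu, mu0, muinf, lam, acy, ncy, ktau, kmu, gcut;
  // inflow
  double vmax, Rin, ramp;
  int bc;                  // 0 inflow/outflow, 1 periodic in z
  int sponge_n; double sponge_sigma;
  int hemo_on; double c1a, ba;
  double fr, fz;
  int order;
  double rho_ref, c_ref;   // outflow anchor state
  double out_relax;        // incoming-characteristic pull strength

  std::vector<double> r;          // signed cell-center radii, size NR
  std::vector<int> mask;          // availability (fluid=1), NR*NZ
  std::vector<signed char> ordz;  // NR*(NZ+1): -2 skip, -1 wall, else order
  std::vector<signed char> ordr;  // (NR+1)*NZ
  std::vector<SolidFill> fills;
};

static inline int ID(const Ctx& c, int i, int j) { return i + c.NR * j; }

static double visc_of(const Ctx& c, double gam_eff) {
  switch (c.rheol) {
  case 0: return c.mu;
  case 1: return c.muinf + (c.mu0 - c.muinf) *
      std::pow(1.0 + std::pow(c.lam * gam_eff, c.acy), (c.ncy - 1.0) / c.acy);
  default: {
    double g = std::max(gam_eff, c.gcut);
    double s = std::sqrt(c.ktau / g) + std::sqrt(c.kmu);
    return s * s;
  }
  }
}

static inline double sound(const Ctx& c, double rho) {
  return c.c0 * std::pow(rho / c.rho0, 0.5 * (c.gam - 1.0));
}
static inline double pres(const Ctx& c, double rho) {
  return c.p0 + c.rho0 * c.c0 * c.c0 / c.gam *
    (std::pow(rho / c.rho0, c.gam) - 1.0);
}

static void build_ctx(Ctx& c, const IntegerMatrix& mask_in, const List& par) {
  c.nr = mask_in.nrow(); c.nz = mask_in.ncol();
  c.g = as<int>(par["ghost"]);
  c.NR = c.nr + 2 * c.g; c.NZ = c.nz + 2 * c.g;
  c.dr = as<double>(par["dr"]); c.dz = as<double>(par["dz"]);
  c.zmin = as<double>(par["zmin"]);
  c.rho0 = as<double>(par["rho0"]); c.c0 = as<double>(par["c0"]);
  c.p0 = as<double>(par["p0"]); c.gam = as<double>(par["gam"]);
  c.rheol = as<int>(par["rheol"]);
  c.mu = as<double>(par["mu"]); c.mu0 = as<double>(par["mu0"]);
  c.muinf = as<double>(par["muinf"]); c.lam = as<double>(par["lambda"]);
  c.acy = as<double>(par["acy"]); c.ncy = as<double>(par["ncy"]);
  c.ktau = as<double>(par["ktau"]); c.kmu = as<double>(par["kmu"]);
  c.gcut = as<double>(par["gcut"]);
  c.vmax = as<double>(par["vmax"]); c.Rin = as<double>(par["Rin"]);
  c.ramp = as<double>(par["ramp"]);
  c.bc = as<int>(par["bc"]);
  c.sponge_n = as<int>(par["sponge_n"]);
  c.sponge_sigma = as<double>(par["sponge_sigma"]);
  c.hemo_on = as<int>(par["hemo_on"]);
  c.c1a = as<double>(par["c1a"]); c.ba = as<double>(par["ba"]);
  c.fr = as<double>(par["fr"]); c.fz = as<double>(par["fz"]);
  c.order = as<int>(par["order"]);
  c.out_relax = as<double>(par["out_relax"]);
  double p_out = as<double>(par["p_out"]);
  c.rho_ref = c.rho0 * std::pow(1.0 + c.gam * (p_out - c.p0) /
                                (c.rho0 * c.c0 * c.c0), 1.0 / c.gam);
  c.c_ref = sound(c, c.rho_ref);

  c.r.assign(c.NR, 0.0);
  for (int i = 0; i < c.NR; ++i) c.r[i] = (i - c.g + 0.5) * c.dr;

  // availability mask with ghost conventions
  c.mask.assign(c.NR * c.NZ, 0);
  for (int j = 0; j < c.nz; ++j)
    for (int i = 0; i < c.nr; ++i)
      c.mask[ID(c, i + c.g, j + c.g)] = mask_in(i, j);
  for (int j = c.g; j < c.g + c.nz; ++j)        // axis mirror rows
    for (int k = 0; k < c.g; ++k)
      c.mask[ID(c, c.g - 1 - k, j)] = c.mask[ID(c, c.g + k, j)];
  for (int k = 0; k < c.g; ++k) {               // z ghosts
    for (int i = 0; i < c.NR; ++i) {
      if (c.bc == 1) {
        c.mask[ID(c, i, k)] = c.mask[ID(c, i, c.nz + k)];
        c.mask[ID(c, i, c.g + c.nz + k)] = c.mask[ID(c, i, c.g + k)];
      } else {
        c.mask[ID(c, i, k)] = c.mask[ID(c, i, c.g)];
        c.mask[ID(c, i, c.g + c.nz + k)] = c.mask[ID(c, i, c.g + c.nz - 1)];
      }
    }
  }

  // face orders, z direction: face jf sits between columns jf-1 and jf
  c.ordz.assign(c.NR * (c.NZ + 1), -2);
  for (int i = c.g; i < c.g + c.nr; ++i) {
    for (int jf = c.g; jf <= c.g + c.nz; ++jf) {
      int a = c.mask[ID(c, i, jf - 1)], b = c.mask[ID(c, i, jf)];
      signed char o;
      if (!a && !b) o = -2;
      else if (!a || !b) o = -1;
      else {
        o = 1;
        for (int oo = (c.order >= 3 ? 3 : 1); oo <= c.order; oo += 2) {
          int k = (oo + 1) / 2;
          bool ok = true;
          for (int m = jf - k; m <= jf + k - 1; ++m)
            if (m < 0 || m >= c.NZ || !c.mask[ID(c, i, m)]) { ok = false; break; }
          if (ok) o = (signed char)oo; else break;
        }
      }
      c.ordz[i + c.NR * jf] = o;
    }
  }
  // radial faces: face if sits between rows if-1 and if
  c.ordr.assign((c.NR + 1) * c.NZ, -2);
  for (int j = c.g; j < c.g + c.nz; ++j) {
    for (int ifc = c.g; ifc <= c.g + c.nr; ++ifc) {
      int a = c.mask[ID(c, ifc - 1, j)], b = c.mask[ID(c, ifc, j)];
      signed char o;
      if (!a && !b) o = -2;
      else if (!a || !b) o = -1;
      else {
        o = 1;
        for (int oo = (c.order >= 3 ? 3 : 1); oo <= c.order; oo += 2) {
          int k = (oo + 1) / 2;
          bool ok = true;
          for (int m = ifc - k; m <= ifc + k - 1; ++m)
            if (m < 0 || m >= c.NR || !c.mask[ID(c, m, j)]) { ok = false; break; }
          if (ok) o = (signed char)oo; else break;
        }
      }
      c.ordr[ifc + (c.NR + 1) * j] = o;
    }
  }

  // narrow fluid spans cannot support the widest stencils (the reflection
  // coupling between the axis ghosts and a nearby wall destabilizes them),
  // so the face order is additionally capped by the local fluid span:
  // >= 10 cells for 7th order, >= 8 for 5th, >= 5 for 3rd
  {
    auto cap_of = [](int span) {
      if (span >= 10) return 7; if (span >= 8) return 5;
      if (span >= 5) return 3; return 1;
    };
    // radial: per-column fluid height
    for (int j = c.g; j < c.g + c.nz; ++j) {
      int h = 0;
      for (int i = c.g; i < c.g + c.nr; ++i) if (c.mask[ID(c, i, j)]) ++h;
      signed char cap = (signed char)cap_of(h);
      for (int ifc = c.g; ifc <= c.g + c.nr; ++ifc) {
        signed char& o = c.ordr[ifc + (c.NR + 1) * j];
        if (o > cap) o = cap;
      }
    }
    // axial: per-row contiguous fluid run length (ghost columns included,
    // since in/outflow ghosts continue the conduit)
    for (int i = c.g; i < c.g + c.nr; ++i) {
      int j = 0;
      while (j < c.NZ) {
        if (!c.mask[ID(c, i, j)]) { ++j; continue; }
        int j2 = j;
        while (j2 < c.NZ && c.mask[ID(c, i, j2)]) ++j2;
        signed char cap = (signed char)cap_of(j2 - j);
        for (int jf = std::max(j, c.g); jf <= std::min(j2, c.g + c.nz); ++jf) {
          signed char& o = c.ordz[i + c.NR * jf];
          if (o > cap) o = cap;
        }
        j = j2;
      }
    }
  }

  // layer-1 solid cells with their fluid neighbors, for no-slip filling
  c.fills.clear();
  int offs[4] = {-1, 1, -c.NR, c.NR};
  for (int j = 1; j < c.NZ - 1; ++j) {
    for (int i = 1; i < c.NR - 1; ++i) {
      int id = ID(c, i, j);
      if (c.mask[id]) continue;
      SolidFill f; f.idx = id; f.ndir = 0;
      for (int d = 0; d < 4; ++d) {
        int nb = id + offs[d];
        if (c.mask[nb]) {
          f.off[f.ndir] = offs[d];
          int nb2 = id + 2 * offs[d];
          bool in2 = true;
          if (offs[d] == -1 && i < 2) in2 = false;
          if (offs[d] == 1 && i > c.NR - 3) in2 = false;
          if (offs[d] == -c.NR && j < 2) in2 = false;
          if (offs[d] == c.NR && j > c.NZ - 3) in2 = false;
          f.has2[f.ndir] = (in2 && c.mask[nb2]) ? 1 : 0;
          f.ndir++;
        }
      }
      if (f.ndir > 0) c.fills.push_back(f);
    }
  }
}

struct Fields {
  std::vector<double> rho, mr, mz, rdl;
};

static double ramp_factor(const Ctx& c, double t) {
  if (c.ramp <= 0) return 1.0;
  double x = t / c.ramp;
  if (x >= 1.0) return 1.0;
  return x * x * (3.0 - 2.0 * x);
}

// fill axis/z ghosts and solid cells (no-slip extrapolation)
static void fill_ghosts(const Ctx& c, Fields& F, double t) {
  // axis parity rows
  for (int j = 0; j < c.NZ; ++j) {
    for (int k = 0; k < c.g; ++k) {
      int ig = c.g - 1 - k, is = c.g + k;
      F.rho[ID(c, ig, j)] = F.rho[ID(c, is, j)];
      F.mz [ID(c, ig, j)] = F.mz [ID(c, is, j)];
      F.rdl[ID(c, ig, j)] = F.rdl[ID(c, is, j)];
      F.mr [ID(c, ig, j)] = -F.mr[ID(c, is, j)];
    }
  }
  if (c.bc == 1) {                     // periodic in z
    for (int k = 0; k < c.g; ++k) {
      for (int i = 0; i < c.NR; ++i) {
        int jl = k, jr = c.g + c.nz + k;
        F.rho[ID(c, i, jl)] = F.rho[ID(c, i, c.nz + k)];
        F.mr [ID(c, i, jl)] = F.mr [ID(c, i, c.nz + k)];
        F.mz [ID(c, i, jl)] = F.mz [ID(c, i, c.nz + k)];
        F.rdl[ID(c, i, jl)] = F.rdl[ID(c, i, c.nz + k)];
        F.rho[ID(c, i, jr)] = F.rho[ID(c, i, c.g + k)];
        F.mr [ID(c, i, jr)] = F.mr [ID(c, i, c.g + k)];
        F.mz [ID(c, i, jr)] = F.mz [ID(c, i, c.g + k)];
        F.rdl[ID(c, i, jr)] = F.rdl[ID(c, i, c.g + k)];
      }
    }
  } else {
    double vfac = ramp_factor(c, t);
    int j0 = c.g, j1 = c.g + c.nz - 1;
    for (int i = 0; i < c.NR; ++i) {
      double rr = std::fabs(c.r[i]);
      // inflow ghosts: Poiseuille velocity, density free (zero gradient)
      double vin = 0.0;
      if (rr <= c.Rin)
        vin = c.vmax * vfac * (1.0 - (rr / c.Rin) * (rr / c.Rin));
      for (int k = 0; k < c.g; ++k) {
        int jg = k;
        double rh = F.rho[ID(c, i, j0)];
        F.rho[ID(c, i, jg)] = rh;
        F.mr [ID(c, i, jg)] = 0.0;
        F.mz [ID(c, i, jg)] = rh * vin;
        F.rdl[ID(c, i, jg)] = 0.0;
      }
      // outflow ghosts: outgoing Riemann invariant extrapolated; the
      // incoming one is mostly extrapolated too (transparent boundary) with
      // a weak pull of the sound speed toward the reference outlet state,
      // which anchors the pressure at a reflection coefficient ~ relax
      double rhoe = F.rho[ID(c, i, j1)];
      double vze = F.mz[ID(c, i, j1)] / rhoe;
      double vre = F.mr[ID(c, i, j1)] / rhoe;
      double dle = F.rdl[ID(c, i, j1)] / rhoe;
      double ce = sound(c, rhoe);
      double k_ = c.out_relax;
      double cg = 0.5 * ((2.0 - k_) * ce + k_ * c.c_ref);
      double vg = vze + k_ * (ce - c.c_ref) / (c.gam - 1.0);
      double rhog = c.rho0 * std::pow(cg / c.c0, 2.0 / (c.gam - 1.0));
      for (int k = 0; k < c.g; ++k) {
        int jg = c.g + c.nz + k;
        F.rho[ID(c, i, jg)] = rhog;
        F.mz [ID(c, i, jg)] = rhog * vg;
        F.mr [ID(c, i, jg)] = rhog * vre;
        F.rdl[ID(c, i, jg)] = rhog * dle;
      }
    }
  }
  // solid layer-1 fill: no-slip quadratic extrapolation of velocity,
  // zero-gradient density and linear damage
  for (size_t s = 0; s < c.fills.size(); ++s) {
    const SolidFill& f = c.fills[s];
    double vrg = 0, vzg = 0, rhg = 0, dlg = 0;
    for (int d = 0; d < f.ndir; ++d) {
      int n1 = f.idx + f.off[d];
      double rh1 = F.rho[n1];
      double vr1 = F.mr[n1] / rh1, vz1 = F.mz[n1] / rh1;
      double dl1 = F.rdl[n1] / rh1;
      if (f.has2[d]) {
        int n2 = f.idx + 2 * f.off[d];
        double rh2 = F.rho[n2];
        double vr2 = F.mr[n2] / rh2, vz2 = F.mz[n2] / rh2;
        vrg += vr2 / 3.0 - 2.0 * vr1;   // quadratic with v=0 at the face
        vzg += vz2 / 3.0 - 2.0 * vz1;
      } else {
        vrg += -vr1;
        vzg += -vz1;
      }
      rhg += rh1; dlg += dl1;
    }
    double inv = 1.0 / f.ndir;
    vrg *= inv; vzg *= inv; rhg *= inv; dlg *= inv;
    F.rho[f.idx] = rhg;
    F.mr [f.idx] = rhg * vrg;
    F.mz [f.idx] = rhg * vzg;
    F.rdl[f.idx] = rhg * dlg;
  }
}

struct Work {
  std::vector<double> vr, vz, p, mu, tau;
  std::vector<double> dvrdr, dvzdr, dvrdz, dvzdz, divv;
  std::vector<double> flz[4], flr[4];
  std::vector<double> dummy1, dummy2, dummy3, dummy4;
  std::vector<double> drho, dmr, dmz, drdl;
  void init(const Ctx& c) {
    int N = c.NR * c.NZ;
    dummy1.assign(N, 0); dummy2.assign(N, 0);
    dummy3.assign(N, 0); dummy4.assign(N, 0);
    vr.assign(N, 0); vz.assign(N, 0); p.assign(N, 0);
    mu.assign(N, 0); tau.assign(N, 0);
    dvrdr.assign(N, 0); dvzdr.assign(N, 0);
    dvrdz.assign(N, 0); dvzdz.assign(N, 0); divv.assign(N, 0);
    for (int f = 0; f < 4; ++f) {
      flz[f].assign(c.NR * (c.NZ + 1), 0);
      flr[f].assign((c.NR + 1) * c.NZ, 0);
    }
    drho.assign(N, 0); dmr.assign(N, 0); dmz.assign(N, 0); drdl.assign(N, 0);
  }
};

static const double* coef_of(int o) {
  switch (o) { case 1: return C1; case 3: return C3; case 5: return C5; case 7: return C7; }
  return 0;
}

// single right-hand-side evaluation; ghosts must be filled already
static void rhs(const Ctx& c, const Fields& F, Work& W, bool scalar_only) {
  const int NR = c.NR;
  const int i0 = c.g, i1 = c.g + c.nr, j0 = c.g, j1 = c.g + c.nz;

  // primitive variables everywhere (ghosts are filled)
  for (int j = 0; j < c.NZ; ++j)
    for (int i = 0; i < NR; ++i) {
      int id = i + NR * j;
      double rh = F.rho[id];
      W.vr[id] = F.mr[id] / rh;
      W.vz[id] = F.mz[id] / rh;
      W.p[id] = pres(c, rh);
    }

  // center velocity gradients (2nd-order central) on an extended window,
  // plus effective shear rate, viscosity, shear-stress magnitude
  for (int j = j0 - 1; j <= j1; ++j) {
    for (int i = i0 - 1; i <= i1; ++i) {
      int id = i + NR * j;
      W.dvrdr[id] = (W.vr[id + 1] - W.vr[id - 1]) / (2 * c.dr);
      W.dvzdr[id] = (W.vz[id + 1] - W.vz[id - 1]) / (2 * c.dr);
      W.dvrdz[id] = (W.vr[id + NR] - W.vr[id - NR]) / (2 * c.dz);
      W.dvzdz[id] = (W.vz[id + NR] - W.vz[id - NR]) / (2 * c.dz);
      double hoop = W.vr[id] / c.r[i];
      if (i == i0 - 1) hoop = W.dvrdr[id];   // below-axis ghost row
      W.divv[id] = W.dvrdr[id] + hoop + W.dvzdz[id];
      double Srr = W.dvrdr[id], Szz = W.dvzdz[id], Stt = hoop;
      double Srz = 0.5 * (W.dvzdr[id] + W.dvrdz[id]);
      double gam_eff = std::sqrt(2.0 * (Srr * Srr + Stt * Stt + Szz * Szz
                                        + 2.0 * Srz * Srz));
      double m = visc_of(c, gam_eff);
      W.mu[id] = m;
      W.tau[id] = m * gam_eff;
    }
  }

  // global dissipation speeds, characteristic-aware: density and the
  // face-normal momentum carry the acoustic speed, the shear momentum and
  // the passive damage field only the advective one (so viscous wall
  // layers are not smeared by acoustic-scale dissipation)
  double az = 0, ar = 0, az_sh = 0, ar_sh = 0;
  for (int j = j0; j < j1; ++j)
    for (int i = i0; i < i1; ++i) {
      int id = i + NR * j;
      if (!c.mask[id]) continue;
      double cs = scalar_only ? 0.0 : sound(c, F.rho[id]);
      az = std::max(az, std::fabs(W.vz[id]) + cs);
      ar = std::max(ar, std::fabs(W.vr[id]) + cs);
      az_sh = std::max(az_sh, std::fabs(W.vz[id]));
      ar_sh = std::max(ar_sh, std::fabs(W.vr[id]));
    }

  // ---- z-direction fluxes ----
  // numerical flux: central average of the left- and right-biased flux
  // interpolations plus matrix-free dissipation on the state,
  //   Fhat = (P(F)+N(F))/2 + a/2 (P(u)-N(u)),
  // where P/N annihilate constants exactly at every order. Reduced-order
  // faces sit in viscous wall layers and use the local advective speed
  // instead of the global acoustic one, which would swamp the physics there.
  // field order: 0 rho, 1 mr, 2 mz, 3 rdl
  {
    // pointwise flux arrays
    std::vector<double>& Z1 = W.dummy1; std::vector<double>& Z2 = W.dummy2;
    std::vector<double>& Z3 = W.dummy3;
    for (int j = 0; j < c.NZ; ++j)
      for (int i = 0; i < NR; ++i) {
        int id = i + NR * j;
        Z1[id] = F.mr[id] * W.vz[id];
        Z2[id] = F.mz[id] * W.vz[id] + W.p[id];
        Z3[id] = F.rdl[id] * W.vz[id];
      }
    for (int jf = j0; jf <= j1; ++jf) {
      for (int i = i0; i < i1; ++i) {
        signed char o = c.ordz[i + NR * jf];
        int fid = i + NR * jf;
        if (o == -2) { for (int f = 0; f < 4; ++f) W.flz[f][fid] = 0; continue; }
        if (o == -1) {
          int idf = c.mask[i + NR * (jf - 1)] ? i + NR * (jf - 1) : i + NR * jf;
          W.flz[0][fid] = 0; W.flz[1][fid] = 0; W.flz[3][fid] = 0;
          W.flz[2][fid] = W.p[idf];            // pressure acts on the wall
          continue;
        }
        int base = i + NR * (jf - 1);
        const double* ck = coef_of(o);
        int k = (o + 1) / 2;
        double p0f = 0, n0f = 0, p1f = 0, n1f = 0, p2f = 0, n2f = 0,
          p3f = 0, n3f = 0, pu0 = 0, nu0 = 0, pu1 = 0, nu1 = 0,
          pu2 = 0, nu2 = 0, pu3 = 0, nu3 = 0;
        for (int m = 0; m < o; ++m) {
          int mm = m - (k - 1);
          int ip = base + NR * mm, in = base + NR * (1 - mm);
          double w = ck[m];
          p0f += w * F.mz[ip];  n0f += w * F.mz[in];
          p1f += w * Z1[ip];    n1f += w * Z1[in];
          p2f += w * Z2[ip];    n2f += w * Z2[in];
          p3f += w * Z3[ip];    n3f += w * Z3[in];
          pu0 += w * F.rho[ip]; nu0 += w * F.rho[in];
          pu1 += w * F.mr[ip];  nu1 += w * F.mr[in];
          pu2 += w * F.mz[ip];  nu2 += w * F.mz[in];
          pu3 += w * F.rdl[ip]; nu3 += w * F.rdl[in];
        }
        W.flz[0][fid] = 0.5 * (p0f + n0f) + 0.5 * az * (pu0 - nu0);
        W.flz[1][fid] = 0.5 * (p1f + n1f) + 0.5 * az_sh * (pu1 - nu1);
        W.flz[2][fid] = 0.5 * (p2f + n2f) + 0.5 * az * (pu2 - nu2);
        W.flz[3][fid] = 0.5 * (p3f + n3f) + 0.5 * az_sh * (pu3 - nu3);
      }
    }
  }

  // ---- radial fluxes: conservative form (1/r) d_r (r Fhat), with the
  // face radius (always >= 0 on updated faces) multiplying the dissipation
  {
    std::vector<double>& G0 = W.dummy1; std::vector<double>& G1 = W.dummy2;
    std::vector<double>& G2 = W.dummy3; std::vector<double>& G3 = W.dummy4;
    for (int j = 0; j < c.NZ; ++j)
      for (int i = 0; i < NR; ++i) {
        int id = i + NR * j;
        double ri_ = c.r[i];
        G0[id] = ri_ * F.mr[id];
        G1[id] = ri_ * (F.mr[id] * W.vr[id] + W.p[id]);
        G2[id] = ri_ * F.mz[id] * W.vr[id];
        G3[id] = ri_ * F.rdl[id] * W.vr[id];
      }
    for (int j = j0; j < j1; ++j) {
      for (int ifc = i0; ifc <= i1; ++ifc) {
        signed char o = c.ordr[ifc + (NR + 1) * j];
        int fid = ifc + (NR + 1) * j;
        if (o == -2) { for (int f = 0; f < 4; ++f) W.flr[f][fid] = 0; continue; }
        double rf = (ifc - c.g) * c.dr;    // face radius
        if (ifc == c.g) {                  // axis face: zero area, zero flux
          for (int f = 0; f < 4; ++f) W.flr[f][fid] = 0;
          continue;
        }
        if (o == -1) {
          int idf = c.mask[(ifc - 1) + NR * j] ? (ifc - 1) + NR * j : ifc + NR * j;
          W.flr[0][fid] = 0; W.flr[2][fid] = 0; W.flr[3][fid] = 0;
          W.flr[1][fid] = rf * W.p[idf];
          continue;
        }
        int base = (ifc - 1) + NR * j;
        const double* ck = coef_of(o);
        int k = (o + 1) / 2;
        double p0f = 0, n0f = 0, p1f = 0, n1f = 0, p2f = 0, n2f = 0,
          p3f = 0, n3f = 0, pu0 = 0, nu0 = 0, pu1 = 0, nu1 = 0,
          pu2 = 0, nu2 = 0, pu3 = 0, nu3 = 0;
        for (int m = 0; m < o; ++m) {
          int mm = m - (k - 1);
          int ip = base + mm, in = base + (1 - mm);
          double w = ck[m];
          p0f += w * G0[ip];    n0f += w * G0[in];
          p1f += w * G1[ip];    n1f += w * G1[in];
          p2f += w * G2[ip];    n2f += w * G2[in];
          p3f += w * G3[ip];    n3f += w * G3[in];
          pu0 += w * F.rho[ip]; nu0 += w * F.rho[in];
          pu1 += w * F.mr[ip];  nu1 += w * F.mr[in];
          pu2 += w * F.mz[ip];  nu2 += w * F.mz[in];
          pu3 += w * F.rdl[ip]; nu3 += w * F.rdl[in];
        }
        W.flr[0][fid] = 0.5 * (p0f + n0f) + 0.5 * ar * rf * (pu0 - nu0);
        W.flr[1][fid] = 0.5 * (p1f + n1f) + 0.5 * ar * rf * (pu1 - nu1);
        W.flr[2][fid] = 0.5 * (p2f + n2f) + 0.5 * ar_sh * rf * (pu2 - nu2);
        W.flr[3][fid] = 0.5 * (p3f + n3f) + 0.5 * ar_sh * rf * (pu3 - nu3);
      }
    }
  }

  // ---- assemble RHS on fluid interior cells ----
  int spz0 = j1 - c.sponge_n;     // first sponge column
  for (int j = j0; j < j1; ++j) {
    double sig = 0.0;
    if (c.bc == 0 && c.sponge_n > 0 && j >= spz0) {
      double xi = (j - spz0 + 1.0) / c.sponge_n;
      sig = c.sponge_sigma * xi * xi;
    }
    for (int i = i0; i < i1; ++i) {
      int id = i + NR * j;
      if (!c.mask[id]) { W.drho[id] = W.dmr[id] = W.dmz[id] = W.drdl[id] = 0; continue; }
      double ri = c.r[i];
      int fz0 = i + NR * j, fz1 = i + NR * (j + 1);
      int fr0 = i + (NR + 1) * j, fr1 = (i + 1) + (NR + 1) * j;
      double adv0 = -(W.flz[0][fz1] - W.flz[0][fz0]) / c.dz
        - (W.flr[0][fr1] - W.flr[0][fr0]) / (ri * c.dr);
      double adv1 = -(W.flz[1][fz1] - W.flz[1][fz0]) / c.dz
        - (W.flr[1][fr1] - W.flr[1][fr0]) / (ri * c.dr);
      double adv2 = -(W.flz[2][fz1] - W.flz[2][fz0]) / c.dz
        - (W.flr[2][fr1] - W.flr[2][fr0]) / (ri * c.dr);
      double adv3 = -(W.flz[3][fz1] - W.flz[3][fz0]) / c.dz
        - (W.flr[3][fr1] - W.flr[3][fr0]) / (ri * c.dr);

      // viscous: face-based stress divergence
      double rfp = ri + 0.5 * c.dr, rfm = ri - 0.5 * c.dr;
      int ide = id + 1, idw = id - 1, idn = id + NR, ids = id - NR;
      // east/west radial faces
      double mue = 0.5 * (W.mu[id] + W.mu[ide]);
      double muw = 0.5 * (W.mu[id] + W.mu[idw]);
      double dvrdr_e = (W.vr[ide] - W.vr[id]) / c.dr;
      double dvrdr_w = (W.vr[id] - W.vr[idw]) / c.dr;
      double dvzdr_e = (W.vz[ide] - W.vz[id]) / c.dr;
      double dvzdr_w = (W.vz[id] - W.vz[idw]) / c.dr;
      double dvrdz_e = 0.5 * (W.dvrdz[id] + W.dvrdz[ide]);
      double dvrdz_w = 0.5 * (W.dvrdz[id] + W.dvrdz[idw]);
      double dvzdz_e = 0.5 * (W.dvzdz[id] + W.dvzdz[ide]);
      double dvzdz_w = 0.5 * (W.dvzdz[id] + W.dvzdz[idw]);
      double vre = 0.5 * (W.vr[id] + W.vr[ide]);
      double vrw = 0.5 * (W.vr[id] + W.vr[idw]);
      double hoop_e = (rfp > 0.25 * c.dr) ? vre / rfp : dvrdr_e;
      double hoop_w = (std::fabs(rfm) > 0.25 * c.dr) ? vrw / rfm : dvrdr_w;
      double dive = dvrdr_e + hoop_e + dvzdz_e;
      double divw = dvrdr_w + hoop_w + dvzdz_w;
      double srr_e = mue * (2.0 * dvrdr_e - (2.0 / 3.0) * dive);
      double srr_w = muw * (2.0 * dvrdr_w - (2.0 / 3.0) * divw);
      double srz_e = mue * (dvzdr_e + dvrdz_e);
      double srz_w = muw * (dvzdr_w + dvrdz_w);
      // north/south axial faces
      double mun = 0.5 * (W.mu[id] + W.mu[idn]);
      double mus = 0.5 * (W.mu[id] + W.mu[ids]);
      double dvrdz_n = (W.vr[idn] - W.vr[id]) / c.dz;
      double dvrdz_s = (W.vr[id] - W.vr[ids]) / c.dz;
      double dvzdz_n = (W.vz[idn] - W.vz[id]) / c.dz;
      double dvzdz_s = (W.vz[id] - W.vz[ids]) / c.dz;
      double dvzdr_n = 0.5 * (W.dvzdr[id] + W.dvzdr[idn]);
      double dvzdr_s = 0.5 * (W.dvzdr[id] + W.dvzdr[ids]);
      double dvrdr_n = 0.5 * (W.dvrdr[id] + W.dvrdr[idn]);
      double dvrdr_s = 0.5 * (W.dvrdr[id] + W.dvrdr[ids]);
      double vrn = 0.5 * (W.vr[id] + W.vr[idn]);
      double vrs = 0.5 * (W.vr[id] + W.vr[ids]);
      double divn = dvrdr_n + vrn / ri + dvzdz_n;
      double divs = dvrdr_s + vrs / ri + dvzdz_s;
      double srz_n = mun * (dvzdr_n + dvrdz_n);
      double srz_s = mus * (dvzdr_s + dvrdz_s);
      double szz_n = mun * (2.0 * dvzdz_n - (2.0 / 3.0) * divn);
      double szz_s = mus * (2.0 * dvzdz_s - (2.0 / 3.0) * divs);
      double stt = W.mu[id] * (2.0 * W.vr[id] / ri - (2.0 / 3.0) * W.divv[id]);

      double visc_r = (rfp * srr_e - rfm * srr_w) / (ri * c.dr)
        + (srz_n - srz_s) / c.dz - stt / ri;
      double visc_z = (rfp * srz_e - rfm * srz_w) / (ri * c.dr)
        + (szz_n - szz_s) / c.dz;

      double src_dl = 0.0;
      if (c.hemo_on)
        src_dl = F.rho[id] * c.c1a * std::pow(W.tau[id], c.ba);

      if (scalar_only) {
        W.drho[id] = 0; W.dmr[id] = 0; W.dmz[id] = 0;
        W.drdl[id] = adv3 + src_dl - sig * 0.0;
      } else {
        W.drho[id] = adv0 - sig * (F.rho[id] - c.rho_ref);
        W.dmr[id] = adv1 + W.p[id] / ri + visc_r + F.rho[id] * c.fr
          - sig * F.mr[id];
        W.dmz[id] = adv2 + visc_z + F.rho[id] * c.fz;
        W.drdl[id] = adv3 + src_dl;
      }
    }
  }
}

static double stable_dt(const Ctx& c, const Fields& F, const Work& W,
                        bool scalar_only, double cfl) {
  double dt = 1e30;
  for (int j = c.g; j < c.g + c.nz; ++j)
    for (int i = c.g; i < c.g + c.nr; ++i) {
      int id = i + c.NR * j;
      if (!c.mask[id]) continue;
      double cs = scalar_only ? 0.0 : sound(c, F.rho[id]);
      double sp = (std::fabs(W.vr[id]) + cs) / c.dr
        + (std::fabs(W.vz[id]) + cs) / c.dz;
      if (sp > 0) dt = std::min(dt, 1.0 / sp);
      if (!scalar_only) {
        double nu = W.mu[id] / F.rho[id];
        double dv = 0.25 / (nu * (1.0 / (c.dr * c.dr) + 1.0 / (c.dz * c.dz)));
        dt = std::min(dt, dv);
      }
    }
  if (scalar_only && dt > 1e29) dt = 1.0;   // no flow: arbitrary step
  return cfl * dt;
}

static void pack_fields(const Ctx& c, const NumericMatrix& rho,
                        const NumericMatrix& mr, const NumericMatrix& mz,
                        const NumericMatrix& rdl, Fields& F) {
  int N = c.NR * c.NZ;
  F.rho.assign(N, c.rho0);
  F.mr.assign(N, 0.0); F.mz.assign(N, 0.0); F.rdl.assign(N, 0.0);
  for (int j = 0; j < c.nz; ++j)
    for (int i = 0; i < c.nr; ++i) {
      int id = ID(c, i + c.g, j + c.g);
      F.rho[id] = rho(i, j); F.mr[id] = mr(i, j);
      F.mz[id] = mz(i, j); F.rdl[id] = rdl(i, j);
    }
}

static NumericMatrix unpack(const Ctx& c, const std::vector<double>& v) {
  NumericMatrix out(c.nr, c.nz);
  for (int j = 0; j < c.nz; ++j)
    for (int i = 0; i < c.nr; ++i)
      out(i, j) = v[ID(c, i + c.g, j + c.g)];
  return out;
}

// [[Rcpp::export]]
List cpp_rhs(NumericMatrix rho, NumericMatrix mr, NumericMatrix mz,
             NumericMatrix rdl, IntegerMatrix mask, List par, double t) {
  Ctx c; build_ctx(c, mask, par);
  Fields F; pack_fields(c, rho, mr, mz, rdl, F);
  fill_ghosts(c, F, t);
  Work W; W.init(c);
  rhs(c, F, W, as<int>(par["scalar_only"]) != 0);
  return List::create(_["drho"] = unpack(c, W.drho),
                      _["dmr"] = unpack(c, W.dmr),
                      _["dmz"] = unpack(c, W.dmz),
                      _["drhoDl"] = unpack(c, W.drdl));
}

// [[Rcpp::export]]
List cpp_fill_ghosts(NumericMatrix rho, NumericMatrix mr, NumericMatrix mz,
                     NumericMatrix rdl, IntegerMatrix mask, List par,
                     double t) {
  Ctx c; build_ctx(c, mask, par);
  Fields F; pack_fields(c, rho, mr, mz, rdl, F);
  fill_ghosts(c, F, t);
  int N = c.NR * c.NZ;
  NumericMatrix Rho(c.NR, c.NZ), Mr(c.NR, c.NZ), Mz(c.NR, c.NZ),
    Rdl(c.NR, c.NZ);
  IntegerMatrix Msk(c.NR, c.NZ);
  for (int k = 0; k < N; ++k) {
    Rho[k] = F.rho[k]; Mr[k] = F.mr[k]; Mz[k] = F.mz[k]; Rdl[k] = F.rdl[k];
    Msk[k] = c.mask[k];
  }
  return List::create(_["rho"] = Rho, _["mr"] = Mr, _["mz"] = Mz,
                      _["rhoDl"] = Rdl, _["mask"] = Msk,
                      _["r"] = NumericVector(c.r.begin(), c.r.end()));
}

// [[Rcpp::export]]
List cpp_advance(NumericMatrix rho, NumericMatrix mr, NumericMatrix mz,
                 NumericMatrix rdl, IntegerMatrix mask, List par,
                 double t0, double t_end, int max_steps, double cfl,
                 double tol, int check_every, int scalar_only_i) {
  Ctx c; build_ctx(c, mask, par);
  bool sc = scalar_only_i != 0;
  Fields F; pack_fields(c, rho, mr, mz, rdl, F);
  Work W; W.init(c);
  int N = c.NR * c.NZ;
  std::vector<double> r0(N), m0r(N), m0z(N), d0(N);
  std::vector<double> pr_mr(N, 0.0), pr_mz(N, 0.0), pr_dl(N, 0.0);

  double t = t0;
  int step = 0;
  bool converged = false;
  int status = 0;                       // 0 running, 1 converged, 2 max steps, 3 diverged
  std::vector<double> res_hist;
  double dt = 0;

  while (step < max_steps && t < t_end) {
    if (step % 10 == 0) {
      fill_ghosts(c, F, t);
      // primitives for dt only
      for (int j = c.g; j < c.g + c.nz; ++j)
        for (int i = c.g; i < c.NR - c.g; ++i) {
          int id = i + c.NR * j;
          W.vr[id] = F.mr[id] / F.rho[id];
          W.vz[id] = F.mz[id] / F.rho[id];
          if (!sc) {
            // viscosity needed for the viscous dt limit: reuse last mu if
            // available, otherwise a cheap local estimate
            if (W.mu[id] <= 0) W.mu[id] = visc_of(c, 0.0);
          }
        }
      dt = stable_dt(c, F, W, sc, cfl);
      if (t + dt > t_end) dt = t_end - t;
    }

    // SSP-RK3
    r0 = F.rho; m0r = F.mr; m0z = F.mz; d0 = F.rdl;
    for (int stage = 0; stage < 3; ++stage) {
      double ts = (stage == 0) ? t : (stage == 1 ? t + dt : t + 0.5 * dt);
      fill_ghosts(c, F, ts);
      rhs(c, F, W, sc);
      double ca, cb;
      if (stage == 0) { ca = 1.0; cb = 1.0; }
      else if (stage == 1) { ca = 0.25; cb = 0.25; }
      else { ca = 2.0 / 3.0; cb = 2.0 / 3.0; }
      for (int j = c.g; j < c.g + c.nz; ++j)
        for (int i = c.g; i < c.g + c.nr; ++i) {
          int id = i + c.NR * j;
          if (!c.mask[id]) continue;
          if (stage == 0) {
            if (!sc) {
              F.rho[id] = r0[id] + dt * W.drho[id];
              F.mr[id] = m0r[id] + dt * W.dmr[id];
              F.mz[id] = m0z[id] + dt * W.dmz[id];
            }
            F.rdl[id] = d0[id] + dt * W.drdl[id];
          } else if (stage == 1) {
            if (!sc) {
              F.rho[id] = 0.75 * r0[id] + 0.25 * (F.rho[id] + dt * W.drho[id]);
              F.mr[id] = 0.75 * m0r[id] + 0.25 * (F.mr[id] + dt * W.dmr[id]);
              F.mz[id] = 0.75 * m0z[id] + 0.25 * (F.mz[id] + dt * W.dmz[id]);
            }
            F.rdl[id] = 0.75 * d0[id] + 0.25 * (F.rdl[id] + dt * W.drdl[id]);
          } else {
            double th = 1.0 / 3.0;
            if (!sc) {
              F.rho[id] = th * r0[id] + (1 - th) * (F.rho[id] + dt * W.drho[id]);
              F.mr[id] = th * m0r[id] + (1 - th) * (F.mr[id] + dt * W.dmr[id]);
              F.mz[id] = th * m0z[id] + (1 - th) * (F.mz[id] + dt * W.dmz[id]);
            }
            F.rdl[id] = th * d0[id] + (1 - th) * (F.rdl[id] + dt * W.drdl[id]);
          }
          if (F.rdl[id] < 0) F.rdl[id] = 0;   // clip scheme undershoots
        }
      (void)ca; (void)cb;
    }
    t += dt; ++step;

    if (step % check_every == 0) {
      double num = 0, den = 0;
      bool bad = false;
      for (int j = c.g; j < c.g + c.nz; ++j)
        for (int i = c.g; i < c.g + c.nr; ++i) {
          int id = i + c.NR * j;
          if (!c.mask[id]) continue;
          if (!std::isfinite(F.rho[id]) || !std::isfinite(F.mr[id]) ||
              !std::isfinite(F.mz[id]) || !std::isfinite(F.rdl[id]))
            bad = true;
          double dmr_ = F.mr[id] - pr_mr[id], dmz_ = F.mz[id] - pr_mz[id];
          double ddl_ = F.rdl[id] - pr_dl[id];
          if (sc) {
            num = std::max(num, std::fabs(ddl_));
            den = std::max(den, std::fabs(F.rdl[id]));
          } else {
            num = std::max(num, std::max(std::fabs(dmr_), std::fabs(dmz_)));
            den = std::max(den, std::max(std::fabs(F.mr[id]),
                                         std::fabs(F.mz[id])));
          }
          pr_mr[id] = F.mr[id]; pr_mz[id] = F.mz[id]; pr_dl[id] = F.rdl[id];
        }
      if (bad) { status = 3; break; }
      double res = num / std::max(den, 1e-300);
      res_hist.push_back(res);
      // only test convergence once any inflow ramp is over
      if (res < tol && t > c.ramp && res_hist.size() > 1) {
        converged = true; status = 1; break;
      }
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (status == 0) status = 2;

  double max_drho = 0;
  for (int j = c.g; j < c.g + c.nz; ++j)
    for (int i = c.g; i < c.g + c.nr; ++i) {
      int id = i + c.NR * j;
      if (!c.mask[id]) continue;
      max_drho = std::max(max_drho, std::fabs(F.rho[id] - c.rho0) / c.rho0);
    }

  return List::create(
    _["rho"] = unpack(c, F.rho), _["mr"] = unpack(c, F.mr),
    _["mz"] = unpack(c, F.mz), _["rhoDl"] = unpack(c, F.rdl),
    _["t"] = t, _["steps"] = step, _["converged"] = converged,
    _["status"] = status, _["dt"] = dt,
    _["residuals"] = NumericVector(res_hist.begin(), res_hist.end()),
    _["max_density_fluctuation"] = max_drho);
}
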