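// Magnetostatics of uniformly x-magnetized rectangular strips (2D, x-z plane)
// via equivalent magnetic surface charge sheets on the two x-edges, plus a
// calibrated power-law background field, and the particle trajectory engine.
//
// Units are SI throughout. Coordinates: x axial from the inlet, z vertical
// with z = 0 at the channel floor; strip tops sit at z = -gap_D.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MU0 = 4e-7 * M_PI;

struct StripSet {
  std::vector<double> xl, xr, zb, zt, M;
  int n;
};

struct Background {
  double B_last, p, xm, L; // B(x) = B_last * ((xm - L)/(xm - x))^p, x-directed
};

// H field and Jacobian of one charged sheet at x = a, z in [z1, z2], surface
// charge density sig (A/m). out: Hx, Hz, dHx/dx, dHx/dz, dHz/dx, dHz/dz.
static inline void sheet_accum(double x, double z, double a, double z1,
                               double z2, double sig, double out[6]) {
  const double dx = x - a;
  const double u1 = z - z1, u2 = z - z2;
  const double r1 = dx * dx + u1 * u1;
  const double r2 = dx * dx + u2 * u2;
  const double c = sig / (2.0 * M_PI);
  out[0] += c * (std::atan(u1 / dx) - std::atan(u2 / dx));
  out[1] += 0.5 * c * std::log(r1 / r2);
  const double jxx = c * (-u1 / r1 + u2 / r2);
  const double jxz = c * (dx / r1 - dx / r2);
  out[2] += jxx;
  out[3] += jxz;
  out[4] += jxz;  // curl-free: dHz/dx == dHx/dz
  out[5] += -jxx; // divergence-free: dHz/dz == -dHx/dx
}

// Total H and Jacobian at (x, z). window < 0 disables strip truncation.
static inline void eval_H(const StripSet &st, const Background &bg, double x,
                          double z, double window, double out[6]) {
  for (int k = 0; k < 6; ++k) out[k] = 0.0;
  for (int i = 0; i < st.n; ++i) {
    if (window > 0.0) {
      double cx = 0.5 * (st.xl[i] + st.xr[i]);
      if (std::fabs(x - cx) > window) continue;
    }
    sheet_accum(x, z, st.xr[i], st.zb[i], st.zt[i], st.M[i], out);
    sheet_accum(x, z, st.xl[i], st.zb[i], st.zt[i], -st.M[i], out);
  }
  if (bg.B_last != 0.0) {
    double Hbg = bg.B_last / MU0 * std::pow((bg.xm - bg.L) / (bg.xm - x), bg.p);
    out[0] += Hbg;
    out[2] += bg.p * Hbg / (bg.xm - x);
  }
}

static StripSet as_strips(const NumericMatrix &strips) {
  StripSet st;
  st.n = strips.nrow();
  for (int i = 0; i < st.n; ++i) {
    st.xl.push_back(strips(i, 0));
    st.xr.push_back(strips(i, 1));
    st.zb.push_back(strips(i, 2));
    st.zt.push_back(strips(i, 3));
    st.M.push_back(strips(i, 4));
  }
  return st;
}

// [[Rcpp::export]]
NumericMatrix cpp_field(NumericVector x, NumericVector z, NumericMatrix strips,
                        double B_last, double p, double xm, double L,
                        double window = -1.0) {
  StripSet st = as_strips(strips);
  Background bg{B_last, p, xm, L};
  int n = x.size();
  NumericMatrix out(n, 6);
  double h[6];
  for (int i = 0; i < n; ++i) {
    eval_H(st, bg, x[i], z[i], window, h);
    for (int k = 0; k < 6; ++k) out(i, k) = MU0 * h[k]; // B and dB/dx_j
  }
  colnames(out) = CharacterVector::create("Bx", "Bz", "dBxdx", "dBxdz",
                                          "dBzdx", "dBzdz");
  return out;
}

// Single-cell trajectory: semi-implicit (drag-implicit) Euler by default,
// plain forward Euler when forward_euler = true. The magnetophoretic force
// is evaluated at the bead-cluster position (x, z + z_force_offset).
// [[Rcpp::export]]
List cpp_simulate(double x0, double z0, NumericMatrix strips, double B_last,
                  double p, double xm, double L, List pars) {
  StripSet st = as_strips(strips);
  Background bg{B_last, p, xm, L};

  const double R = pars["radius"];
  const double nb = pars["n_b"];
  const double Fcoef = pars["force_coef"]; // n_b * mu0 * V_b * shape factor
  const double mass = pars["mass"];
  const double gamma = pars["gamma"]; // 6 pi eta R
  const double u_mean = pars["u_mean"];
  const double hch = pars["channel_height"];
  const double mu_f = pars["friction_mu"];
  const double dt = pars["dt"];
  const double max_time = pars["max_time"];
  const double zoff = pars["z_force_offset"];
  const double window = pars["window"];
  const double g_force = pars["g_force"]; // signed vertical body force, N
  const bool forward = pars["forward_euler"];
  const double veps = pars["static_eps"];       // static/dynamic threshold m/s
  const double ceps = pars["capture_eps"];      // capture speed threshold m/s
  const int csteps = pars["capture_steps"];     // consecutive quiet steps
  const int record_every = pars["record_every"];

  double x = x0, z = z0, vx = 0.0, vz = 0.0, tnow = 0.0;
  bool contact = (z <= R + 1e-15);
  int quiet = 0;
  long nmax = (long)std::ceil(max_time / dt) + 2;

  std::vector<double> rt, rx, rz, rvx, rvz, rc;
  auto record = [&]() {
    rt.push_back(tnow); rx.push_back(x); rz.push_back(z);
    rvx.push_back(vx); rvz.push_back(vz); rc.push_back(contact ? 1.0 : 0.0);
  };
  record();

  int outcome = 2; // 0 captured, 1 passed_through, 2 indeterminate
  double cache_x = NA_REAL, cache_z = NA_REAL, Fmx = 0.0, Fmz = 0.0;
  double h6[6];
  long step = 0;
  for (step = 1; step <= nmax; ++step) {
    if (nb > 0.0) {
      double zf = z + zoff;
      if (x != cache_x || zf != cache_z) {
        eval_H(st, bg, x, zf, window, h6);
        // (H . grad) H, then force
        double ffx = h6[2] * h6[0] + h6[3] * h6[1];
        double ffz = h6[4] * h6[0] + h6[5] * h6[1];
        Fmx = Fcoef * ffx;
        Fmz = Fcoef * ffz;
        cache_x = x; cache_z = zf;
      }
    }
    double Fx = Fmx, Fz = Fmz + g_force;
    if (!R_finite(Fx) || !R_finite(Fz))
      stop("non-finite force at x=%g, z=%g", x, z);
    double uf = 6.0 * u_mean * (z / hch) * (1.0 - z / hch);
    double vx_new, vz_new;
    if (contact) {
      double N = std::max(0.0, -Fz);
      double Fapp = Fx + gamma * (uf - vx);
      if (std::fabs(vx) <= veps && std::fabs(Fapp) <= mu_f * N) {
        vx_new = 0.0;
      } else {
        double dir = (std::fabs(vx) > veps) ? (vx > 0 ? 1.0 : -1.0)
                                            : (Fapp > 0 ? 1.0 : -1.0);
        double Ffr = -dir * mu_f * N;
        vx_new = forward
          ? vx + dt / mass * (Fx + Ffr + gamma * (uf - vx))
          : (mass * vx + dt * (Fx + Ffr + gamma * uf)) / (mass + dt * gamma);
        if (vx_new * dir < 0.0) vx_new = 0.0; // friction cannot reverse motion
      }
      vz_new = forward ? vz + dt / mass * (Fz - gamma * vz)
                       : (mass * vz + dt * Fz) / (mass + dt * gamma);
    } else {
      vx_new = forward
        ? vx + dt / mass * (Fx + gamma * (uf - vx))
        : (mass * vx + dt * (Fx + gamma * uf)) / (mass + dt * gamma);
      vz_new = forward ? vz + dt / mass * (Fz - gamma * vz)
                       : (mass * vz + dt * Fz) / (mass + dt * gamma);
    }
    x += dt * vx_new;
    z += dt * vz_new;
    if (z <= R) { // floor clamp with normal reaction; sets contact
      z = R;
      if (vz_new < 0.0) vz_new = 0.0;
      contact = true;
    } else {
      contact = false;
    }
    if (z >= hch - R) { // frictionless ceiling
      z = hch - R;
      if (vz_new > 0.0) vz_new = 0.0;
    }
    vx = vx_new; vz = vz_new; tnow += dt;

    if (contact && std::fabs(vx) < ceps && std::fabs(vz) < ceps) ++quiet;
    else quiet = 0;

    if (step % record_every == 0) record();
    if (quiet >= csteps) { outcome = 0; break; }
    if (x >= L) { outcome = 1; break; }
    if (tnow >= max_time) { outcome = 2; break; }
  }
  record();
  int nrec = rt.size();
  NumericMatrix path(nrec, 6);
  for (int i = 0; i < nrec; ++i) {
    path(i, 0) = rt[i]; path(i, 1) = rx[i]; path(i, 2) = rz[i];
    path(i, 3) = rvx[i]; path(i, 4) = rvz[i]; path(i, 5) = rc[i];
  }
  colnames(path) = CharacterVector::create("t", "x", "z", "vx", "vz",
                                           "contact");
  return List::create(_["outcome"] = outcome, _["x"] = x, _["z"] = z,
                      _["vx"] = vx, _["vz"] = vz, _["time"] = tnow,
                      _["n_steps"] = (double)step, _["path"] = path);
}
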