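// Staggered-grid (MAC) fractional-step solver for unsteady incompressible
// Newtonian flow through a rasterized graft lumen.
//
// Modes: axisymmetric r-z (radial metric terms, axis at j = 0) or planar
// symmetric half-channel y-z (unit metrics, symmetry plane at j = 0).
//
// Layout (0-based):
//   p(i,j): nz x nr cell centres, fluid iff j < np[i]
//   u(i,j): axial velocity at z-faces, (nz+1) x nr, fluid iff j < nu[i]
//   v(i,j): radial velocity at r-faces, nz x (nr+1), fluid iff 1 <= j <= np[i]-1
//
// Wall: ghost-cell no-slip at the analytic lumen radius. The top fluid u
// node in each column sits a gap hu (clamped to [0.5, 1.5] dr) below the
// wall; the ghost value u_ghost = u * (1 - dr/hu) makes the linear profile
// vanish at the wall. hu = 0.5 dr reproduces the classic mirrored ghost.
//
// Boundary conditions: flat (plug) inlet velocity, fixed static pressure at
// the outlet with zero-gradient velocity, no-slip rigid walls, symmetry at
// the axis. Pressure Poisson equation solved by Jacobi-preconditioned
// conjugate gradients, warm-started from the previous step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Grid {
  int nz, nr;
  double dz, dr;
  bool axisym;
  std::vector<int> np, nu;      // fluid cell counts per p/u column
  std::vector<double> hu;       // wall gap at top u node, per u column
  std::vector<double> wf, wc;   // radial metric at faces / centres
};

static inline int iu(const Grid& g, int i, int j) { return i + j * (g.nz + 1); }
static inline int ip(const Grid& g, int i, int j) { return i + j * g.nz; }
static inline int iv(const Grid& g, int i, int j) { return i + j * g.nz; }

// divergence of (u, v) in fluid cell (i, j)
static inline double divergence(const Grid& g, const std::vector<double>& u,
                                const std::vector<double>& v, int i, int j) {
  double dudz = (u[iu(g, i + 1, j)] - u[iu(g, i, j)]) / g.dz;
  double vn = (j + 1 <= g.nr) ? v[iv(g, i, j + 1)] : 0.0;
  double vs = v[iv(g, i, j)];
  double dvdr = (g.wf[j + 1] * vn - g.wf[j] * vs) / (g.wc[j] * g.dr);
  if (!g.axisym && j == 0) dvdr = (vn - 0.0) / g.dr;  // symmetry plane: vs = 0
  return dudz + dvdr;
}

// y = A x for the pressure Poisson system (SPD, Dirichlet at outlet east)
static void apply_poisson(const Grid& g, const std::vector<double>& x,
                          std::vector<double>& y) {
  const double Tz = g.dr / g.dz, Tr = g.dz / g.dr;
  for (int j = 0; j < g.nr; ++j) {
    for (int i = 0; i < g.nz; ++i) {
      if (j >= g.np[i]) { y[ip(g, i, j)] = 0.0; continue; }
      double acc = 0.0, xc = x[ip(g, i, j)];
      // west / east
      if (i > 0 && j < g.np[i - 1]) acc += g.wc[j] * Tz * (x[ip(g, i - 1, j)] - xc);
      if (i < g.nz - 1 && j < g.np[i + 1]) acc += g.wc[j] * Tz * (x[ip(g, i + 1, j)] - xc);
      if (i == g.nz - 1) acc += g.wc[j] * Tz * (-2.0 * xc);  // Dirichlet ghost (RHS carries p_out)
      // south / north
      if (j > 0) acc += g.wf[j] * Tr * (x[ip(g, i, j - 1)] - xc);
      if (j + 1 < g.np[i]) acc += g.wf[j + 1] * Tr * (x[ip(g, i, j + 1)] - xc);
      y[ip(g, i, j)] = -acc;  // negated so A is positive definite
    }
  }
}

static void poisson_diag(const Grid& g, std::vector<double>& d) {
  const double Tz = g.dr / g.dz, Tr = g.dz / g.dr;
  for (int j = 0; j < g.nr; ++j) {
    for (int i = 0; i < g.nz; ++i) {
      if (j >= g.np[i]) { d[ip(g, i, j)] = 1.0; continue; }
      double acc = 0.0;
      if (i > 0 && j < g.np[i - 1]) acc += g.wc[j] * Tz;
      if (i < g.nz - 1 && j < g.np[i + 1]) acc += g.wc[j] * Tz;
      if (i == g.nz - 1) acc += 2.0 * g.wc[j] * Tz;
      if (j > 0) acc += g.wf[j] * Tr;
      if (j + 1 < g.np[i]) acc += g.wf[j + 1] * Tr;
      d[ip(g, i, j)] = acc;
    }
  }
}

// Preconditioned CG; returns iterations used, -1 on non-convergence.
static int solve_pressure(const Grid& g, std::vector<double>& p,
                          const std::vector<double>& b,
                          const std::vector<double>& diag,
                          double tol, int maxit,
                          std::vector<double>& r, std::vector<double>& z,
                          std::vector<double>& q, std::vector<double>& Aq) {
  const int n = g.nz * g.nr;
  apply_poisson(g, p, Aq);
  double bnorm = 0.0;
  for (int k = 0; k < n; ++k) { r[k] = b[k] - Aq[k]; bnorm += b[k] * b[k]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm < 1e-300) return 0;
  double rz = 0.0, rnorm = 0.0;
  for (int k = 0; k < n; ++k) {
    z[k] = r[k] / diag[k]; q[k] = z[k];
    rz += r[k] * z[k]; rnorm += r[k] * r[k];
  }
  if (std::sqrt(rnorm) <= tol * bnorm) return 0;
  for (int it = 1; it <= maxit; ++it) {
    apply_poisson(g, q, Aq);
    double qAq = 0.0;
    for (int k = 0; k < n; ++k) qAq += q[k] * Aq[k];
    if (qAq <= 0.0) return -1;
    double alpha = rz / qAq;
    rnorm = 0.0;
    for (int k = 0; k < n; ++k) {
      p[k] += alpha * q[k];
      r[k] -= alpha * Aq[k];
      rnorm += r[k] * r[k];
    }
    if (std::sqrt(rnorm) <= tol * bnorm) return it;
    double rz_new = 0.0;
    for (int k = 0; k < n; ++k) { z[k] = r[k] / diag[k]; rz_new += r[k] * z[k]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int k = 0; k < n; ++k) q[k] = z[k] + beta * q[k];
  }
  return -1;
}

static inline double blend(double central, double upwind, double beta) {
  return (1.0 - beta) * central + beta * upwind;
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(int nz, int nr, double dz, double dr, bool axisym,
                   IntegerVector np_in, IntegerVector nu_in, NumericVector hu_in,
                   double rho, double mu, double u_in, double p_out,
                   double cfl, double washout_time, double sampling_time,
                   int n_samples, double beta_up, double poisson_tol,
                   double steady_tol, double max_dt, int max_steps) {
  Grid g;
  g.nz = nz; g.nr = nr; g.dz = dz; g.dr = dr; g.axisym = axisym;
  g.np.assign(np_in.begin(), np_in.end());
  g.nu.assign(nu_in.begin(), nu_in.end());
  g.hu.assign(hu_in.begin(), hu_in.end());
  g.wf.resize(nr + 1); g.wc.resize(nr);
  for (int j = 0; j <= nr; ++j) g.wf[j] = axisym ? j * dr : 1.0;
  for (int j = 0; j < nr; ++j) g.wc[j] = axisym ? (j + 0.5) * dr : 1.0;

  const double nu_visc = mu / rho;
  const int nup = (nz + 1) * nr, npp = nz * nr, nvp = nz * (nr + 1);
  std::vector<double> u(nup, 0.0), v(nvp, 0.0), us(nup, 0.0), vs(nvp, 0.0);
  std::vector<double> p(npp, 0.0), b(npp, 0.0), diag(npp, 1.0);
  std::vector<double> r(npp), z(npp), q(npp), Aq(npp);
  poisson_diag(g, diag);

  // initial condition: plug flow scaled per column to be near-solenoidal
  double area_in = 0.0;
  for (int j = 0; j < g.nu[0]; ++j) area_in += g.wc[j] * dr;
  for (int i = 0; i <= nz; ++i) {
    double area_i = 0.0;
    for (int j = 0; j < g.nu[i]; ++j) area_i += g.wc[j] * dr;
    double ui = (area_i > 0.0) ? u_in * area_in / area_i : 0.0;
    for (int j = 0; j < g.nu[i]; ++j) u[iu(g, i, j)] = ui;
  }

  const double sample_dt = sampling_time / n_samples;
  NumericVector u_samp(static_cast<R_xlen_t>(nup) * n_samples);
  NumericVector v_samp(static_cast<R_xlen_t>(nvp) * n_samples);
  NumericVector p_samp(static_cast<R_xlen_t>(npp) * n_samples);
  NumericVector t_samp(n_samples), div_samp(n_samples);
  NumericVector flux_in(n_samples), flux_out(n_samples);

  double t = 0.0, dt = max_dt;
  int step = 0, taken = 0, cg_total = 0, steady_at = -1;
  const double u_ref = std::max(std::fabs(u_in), 1e-12);
  std::vector<double> u_chk(u);
  const int chk_every = 25;
  bool steady = false;
  const double dt_diff_lim = 0.125 * std::min(dz, dr) * std::min(dz, dr) / nu_visc;

  auto record = [&](int k) {
    for (int m = 0; m < nup; ++m) u_samp[static_cast<R_xlen_t>(k) * nup + m] = u[m];
    for (int m = 0; m < nvp; ++m) v_samp[static_cast<R_xlen_t>(k) * nvp + m] = v[m];
    for (int m = 0; m < npp; ++m) p_samp[static_cast<R_xlen_t>(k) * npp + m] = p[m] + p_out;
    t_samp[k] = t;
    double dmax = 0.0, fin = 0.0, fout = 0.0;
    for (int i = 0; i < nz; ++i)
      for (int j = 0; j < g.np[i]; ++j)
        dmax = std::max(dmax, std::fabs(divergence(g, u, v, i, j)));
    for (int j = 0; j < g.nu[0]; ++j) fin += u[iu(g, 0, j)] * g.wc[j] * dr;
    for (int j = 0; j < g.nu[nz]; ++j) fout += u[iu(g, nz, j)] * g.wc[j] * dr;
    div_samp[k] = dmax; flux_in[k] = fin; flux_out[k] = fout;
  };

  int n_recorded = 0;
  double next_sample = washout_time;
  const double t_end = washout_time + sampling_time;

  while (taken < n_samples || t < t_end) {
    if (n_recorded >= n_samples) break;
    if (++step > max_steps)
      stop("solver exceeded max_steps (%d) before completing the sampling window", max_steps);

    // adaptive time step from current CFL and the explicit diffusion limit
    if (step % 10 == 1) {
      double umax = 1e-12, vmax = 1e-12;
      for (int m = 0; m < nup; ++m) umax = std::max(umax, std::fabs(u[m]));
      for (int m = 0; m < nvp; ++m) vmax = std::max(vmax, std::fabs(v[m]));
      dt = std::min({cfl * dz / umax, cfl * dr / vmax, dt_diff_lim, max_dt});
    }

    // ---- predictor: explicit advection + diffusion -----------------------
    for (int i = 1; i < nz; ++i) {
      int Ju = g.nu[i];
      for (int j = 0; j < Ju; ++j) {
        double uc = u[iu(g, i, j)];
        double uW = u[iu(g, i - 1, j)], uE = u[iu(g, i + 1, j)];
        double uS = (j == 0) ? uc : u[iu(g, i, j - 1)];
        double uN;
        if (j == Ju - 1) uN = uc * (1.0 - dr / g.hu[i]);   // ghost across the wall
        else uN = u[iu(g, i, j + 1)];
        double vbar = 0.25 * (v[iv(g, i - 1, j)] + v[iv(g, i - 1, j + 1)] +
                              v[iv(g, i, j)] + v[iv(g, i, j + 1)]);
        double ddz_c = (uE - uW) / (2.0 * dz);
        double ddz_u = (uc > 0.0) ? (uc - uW) / dz : (uE - uc) / dz;
        double ddr_c = (uN - uS) / (2.0 * dr);
        double ddr_u = (vbar > 0.0) ? (uc - uS) / dr : (uN - uc) / dr;
        double adv = uc * blend(ddz_c, ddz_u, beta_up) +
                     vbar * blend(ddr_c, ddr_u, beta_up);
        double lap_z = (uE - 2.0 * uc + uW) / (dz * dz);
        double lap_r = (g.wf[j + 1] * (uN - uc) - g.wf[j] * (uc - uS)) /
                       (g.wc[j] * dr * dr);
        us[iu(g, i, j)] = uc + dt * (-adv + nu_visc * (lap_z + lap_r));
      }
      for (int j = Ju; j < nr; ++j) us[iu(g, i, j)] = 0.0;
    }
    // inlet plug, outlet zero-gradient
    for (int j = 0; j < nr; ++j) {
      us[iu(g, 0, j)] = (j < g.nu[0]) ? u_in : 0.0;
      us[iu(g, nz, j)] = (j < g.nu[nz]) ? us[iu(g, nz - 1, j)] : 0.0;
    }

    for (int i = 0; i < nz; ++i) {
      int Jp = g.np[i];
      for (int j = 1; j < Jp; ++j) {
        double vc = v[iv(g, i, j)];
        double vW = (i == 0) ? -vc : v[iv(g, i - 1, j)];
        double vE = (i == nz - 1) ? vc : v[iv(g, i + 1, j)];
        double vS = v[iv(g, i, j - 1)];
        double vN = (j + 1 <= nr) ? v[iv(g, i, j + 1)] : 0.0;
        double ubar = 0.25 * (u[iu(g, i, j - 1)] + u[iu(g, i, j)] +
                              u[iu(g, i + 1, j - 1)] + u[iu(g, i + 1, j)]);
        double ddz_c = (vE - vW) / (2.0 * dz);
        double ddz_u = (ubar > 0.0) ? (vc - vW) / dz : (vE - vc) / dz;
        double ddr_c = (vN - vS) / (2.0 * dr);
        double ddr_u = (vc > 0.0) ? (vc - vS) / dr : (vN - vc) / dr;
        double adv = ubar * blend(ddz_c, ddz_u, beta_up) +
                     vc * blend(ddr_c, ddr_u, beta_up);
        double lap_z = (vE - 2.0 * vc + vW) / (dz * dz);
        double lap_r;
        if (axisym) {
          // d/dr[(1/r) d(r v)/dr] via compact conservative differencing
          double Hn = (g.wf[j + 1] * vN - g.wf[j] * vc) / (g.wc[j] * dr);
          double Hs = (g.wf[j] * vc - g.wf[j - 1] * vS) / (g.wc[j - 1] * dr);
          lap_r = (Hn - Hs) / dr;
        } else {
          lap_r = (vN - 2.0 * vc + vS) / (dr * dr);
        }
        vs[iv(g, i, j)] = vc + dt * (-adv + nu_visc * (lap_z + lap_r));
      }
      vs[iv(g, i, 0)] = 0.0;
      for (int j = Jp; j <= nr; ++j) vs[iv(g, i, j)] = 0.0;
    }

    // ---- pressure Poisson ------------------------------------------------
    for (int i = 0; i < nz; ++i) {
      for (int j = 0; j < nr; ++j) {
        if (j >= g.np[i]) { b[ip(g, i, j)] = 0.0; continue; }
        // A is the negated Laplacian (SPD), so the divergence source flips
        // sign; p is the perturbation about the outlet reference, so the
        // Dirichlet ghost is homogeneous and contributes nothing to b
        b[ip(g, i, j)] = -(rho / dt) * divergence(g, us, vs, i, j) *
                         g.wc[j] * dr * dz;
      }
    }
    int iters = solve_pressure(g, p, b, diag, poisson_tol, 4000, r, z, q, Aq);
    if (iters < 0)
      stop("pressure Poisson solve failed to converge (step %d, t = %g s)", step, t);
    cg_total += iters;

    // ---- projection ------------------------------------------------------
    for (int i = 1; i < nz; ++i)
      for (int j = 0; j < g.nu[i]; ++j)
        u[iu(g, i, j)] = us[iu(g, i, j)] -
          dt / rho * (p[ip(g, i, j)] - p[ip(g, i - 1, j)]) / dz;
    for (int j = 0; j < nr; ++j) {
      u[iu(g, 0, j)] = (j < g.nu[0]) ? u_in : 0.0;
      u[iu(g, nz, j)] = (j < g.nu[nz])
        ? us[iu(g, nz, j)] + dt / rho * 2.0 * p[ip(g, nz - 1, j)] / dz
        : 0.0;
    }
    for (int i = 0; i < nz; ++i) {
      for (int j = 1; j < g.np[i]; ++j)
        v[iv(g, i, j)] = vs[iv(g, i, j)] -
          dt / rho * (p[ip(g, i, j)] - p[ip(g, i, j - 1)]) / dr;
      v[iv(g, i, 0)] = 0.0;
      for (int j = g.np[i]; j <= nr; ++j) v[iv(g, i, j)] = 0.0;
    }
    t += dt;

    // ---- stability / steadiness checks ----------------------------------
    if (step % chk_every == 0) {
      double chg = 0.0; bool bad = false;
      for (int m = 0; m < nup; ++m) {
        if (!std::isfinite(u[m])) { bad = true; break; }
        chg = std::max(chg, std::fabs(u[m] - u_chk[m]));
      }
      if (bad) stop("solver produced non-finite velocity at t = %g s (step %d); reduce CFL", t, step);
      u_chk = u;
      if (steady_tol > 0.0 && chg < steady_tol * u_ref && step > 2 * chk_every) {
        steady = true; steady_at = step;
      }
      if (step % 1000 == 0) Rcpp::checkUserInterrupt();
    }

    // ---- sampling --------------------------------------------------------
    if (t >= next_sample - 1e-12 && n_recorded < n_samples) {
      record(n_recorded);
      ++n_recorded; ++taken;
      next_sample = washout_time + n_recorded * sample_dt;
    }
    if (steady) {
      // flow no longer changes: replicate the steady field over the
      // remaining sampling window (fluctuations are identically zero)
      while (n_recorded < n_samples) {
        t = washout_time + n_recorded * sample_dt;
        record(n_recorded);
        ++n_recorded;
      }
      break;
    }
  }

  return List::create(
    _["u"] = u_samp, _["v"] = v_samp, _["p"] = p_samp,
    _["times"] = t_samp, _["div_max"] = div_samp,
    _["flux_in"] = flux_in, _["flux_out"] = flux_out,
    _["n_steps"] = step, _["cg_iterations"] = cg_total,
    _["steady"] = steady, _["steady_step"] = steady_at,
    _["dt_final"] = dt);
}
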