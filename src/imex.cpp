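// Core IMEX (implicit diffusion / explicit reaction) integrator for
// mass-conserved activator-substrate (MCAS) reaction-diffusion models.
//
// State layout: npts x nspecies, column-major. 2D grids are indexed
// p = x + nx*y (x fastest); diffusion is applied by operator splitting
// (backward-Euler tridiagonal sweeps per direction, ADI-style in 2D).
// Internal no-flux walls sit on x-interfaces; a wall at interface i
// removes the coupling between columns i and i+1 (1-based; i == nx is
// the periodic seam). Each sweep matrix has unit column sums, so the
// implicit solve conserves per-species mass to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tridiagonal (optionally cyclic) systems, factored once per (dt, species)
// ---------------------------------------------------------------------------

struct TriSys {
  int n = 0;
  bool cyclic = false;
  std::vector<double> a, c;      // sub / super diagonal (corner removed)
  std::vector<double> cp, invm;  // Thomas factorisation
  std::vector<double> z;         // Sherman-Morrison correction column
  double alpha = 0, beta = 0, gamma = 0;

  // s = dt * D / h^2 ; bc: 0 periodic, 1 no-flux;
  // wall_after[i] (0-based): no coupling between cells i and i+1
  // (index n-1 refers to the periodic seam).
  void build(int n_, double s, int bc, const std::vector<char>& wall_after) {
    n = n_;
    a.assign(n, 0.0);
    c.assign(n, 0.0);
    std::vector<double> b(n, 1.0);
    cyclic = false;
    alpha = beta = 0.0;
    if (n > 1) {
      for (int i = 0; i < n - 1; ++i) {
        bool coupled = wall_after.empty() || !wall_after[i];
        if (coupled) {
          b[i] += s; c[i] = -s;
          b[i + 1] += s; a[i + 1] = -s;
        }
      }
      bool seam = (bc == 0) && n > 2 &&
                  (wall_after.empty() || !wall_after[n - 1]);
      if (seam) {
        b[0] += s; b[n - 1] += s;
        alpha = -s;  // A[n-1][0]
        beta = -s;   // A[0][n-1]
        cyclic = true;
      }
    }
    factor(b);
  }

  void factor(std::vector<double> b) {
    if (cyclic) {
      gamma = -b[0];
      b[0] -= gamma;
      b[n - 1] -= alpha * beta / gamma;
    }
    cp.assign(n, 0.0);
    invm.assign(n, 0.0);
    invm[0] = 1.0 / b[0];
    cp[0] = c[0] * invm[0];
    for (int i = 1; i < n; ++i) {
      double m = b[i] - a[i] * cp[i - 1];
      invm[i] = 1.0 / m;
      cp[i] = c[i] * invm[i];
    }
    if (cyclic) {
      z.assign(n, 0.0);
      z[0] = gamma;
      z[n - 1] = alpha;
      solve_plain(z.data(), 1);
    }
  }

  void solve_plain(double* d, int stride) const {
    d[0] *= invm[0];
    for (int i = 1; i < n; ++i)
      d[i * stride] = (d[i * stride] - a[i] * d[(i - 1) * stride]) * invm[i];
    for (int i = n - 2; i >= 0; --i)
      d[i * stride] -= cp[i] * d[(i + 1) * stride];
  }

  void solve(double* d, int stride) const {
    if (n == 1) return;  // b == 1, no diffusion coupling
    solve_plain(d, stride);
    if (cyclic) {
      double x0 = d[0], xn = d[(n - 1) * stride];
      double fact = (x0 + beta * xn / gamma) /
                    (1.0 + z[0] + beta * z[n - 1] / gamma);
      for (int i = 0; i < n; ++i) d[i * stride] -= fact * z[i];
    }
  }
};

// ---------------------------------------------------------------------------
// Reaction kernels (per grid point, vectorised over points)
// kernel ids: 0 none, 1 minimal, 2 indirect-substrate,
//             3 mechanistic (positive feedback), 4 mechanistic + NFB
// ---------------------------------------------------------------------------

static inline double hill(double vmax, double x, double nexp, double h) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, nexp);
  return vmax * xn / (std::pow(h, nexp) + xn);
}

static void react_all(int kernel, const double* p, const double* U, double* R,
                      int npts, int ns) {
  switch (kernel) {
  case 0:
    std::memset(R, 0, sizeof(double) * (size_t)npts * ns);
    break;
  case 1: {  // minimal: (u, v); p = (a, b)
    const double a = p[0], b = p[1];
    const double *u = U, *v = U + npts;
    double *ru = R, *rv = R + npts;
    for (int i = 0; i < npts; ++i) {
      double f = a * u[i] * u[i] * v[i] - b * u[i];
      ru[i] = f;
      rv[i] = -f;
    }
    break;
  }
  case 2: {  // indirect substrate: (u, v, vi); p = (a, b, c, d)
    const double a = p[0], b = p[1], c = p[2], d = p[3];
    const double *u = U, *v = U + npts, *vi = U + 2 * npts;
    double *ru = R, *rv = R + npts, *rvi = R + 2 * npts;
    for (int i = 0; i < npts; ++i) {
      double f = a * u[i] * u[i] * v[i] - b * u[i];
      ru[i] = f - c * u[i];
      rv[i] = -f + d * vi[i];
      rvi[i] = c * u[i] - d * vi[i];
    }
    break;
  }
  case 3: {  // mechanistic PF: (Cdc42T, Cdc42Dm, BemGEF42, BemGEFm, Cdc42Dc, BemGEFc)
             // p = (k1a,k1b,k2a,k2b,k3,k4a,k4b,k5a,k5b,k7,eta)
    const double k1a = p[0], k1b = p[1], k2a = p[2], k2b = p[3], k3 = p[4],
                 k4a = p[5], k4b = p[6], k5a = p[7], k5b = p[8], k7 = p[9],
                 eta = p[10];
    const double *T = U, *Dm = U + npts, *B42 = U + 2 * npts,
                 *Bm = U + 3 * npts, *Dc = U + 4 * npts, *Bc = U + 5 * npts;
    double *rT = R, *rDm = R + npts, *rB42 = R + 2 * npts,
           *rBm = R + 3 * npts, *rDc = R + 4 * npts, *rBc = R + 5 * npts;
    for (int i = 0; i < npts; ++i) {
      double act = (k2a * Bm[i] + k3 * B42[i]) * Dm[i];
      rT[i] = act - (k2b + k4a * Bm[i] + k7 * Bc[i]) * T[i] + k4b * B42[i];
      rDm[i] = k2b * T[i] - act - k5b * Dm[i] + k5a * Dc[i];
      rB42[i] = (k4a * Bm[i] + k7 * Bc[i]) * T[i] - k4b * B42[i];
      rBm[i] = k1a * Bc[i] - k1b * Bm[i] + k4b * B42[i] - k4a * Bm[i] * T[i];
      rDc[i] = eta * (k5b * Dm[i] - k5a * Dc[i]);
      rBc[i] = eta * (k1b * Bm[i] - k1a * Bc[i] - k7 * Bc[i] * T[i]);
    }
    break;
  }
  case 4: {  // mechanistic + GEF-phosphorylation negative feedback
             // species: T, Dm42, B42, Bm, Dc42, Bc, Bm*, Bc*, B42*
             // p = (k1a..k7,eta, k8max,k8n,k8h, k9max,k9n,k9h, k8arg,k9arg)
             // k8arg: 0 -> BemGEF42_t, 1 -> BemGEF_mt (literal reading)
             // k9arg: 0 -> BemGEF*_c,  1 -> BemGEF*_m (literal reading)
    const double k1a = p[0], k1b = p[1], k2a = p[2], k2b = p[3], k3 = p[4],
                 k4a = p[5], k4b = p[6], k5a = p[7], k5b = p[8], k7 = p[9],
                 eta = p[10], k8max = p[11], k8n = p[12], k8h = p[13],
                 k9max = p[14], k9n = p[15], k9h = p[16];
    const int k8arg = (int)p[17], k9arg = (int)p[18];
    const double *T = U, *Dm = U + npts, *B42 = U + 2 * npts,
                 *Bm = U + 3 * npts, *Dc = U + 4 * npts, *Bc = U + 5 * npts,
                 *Bms = U + 6 * npts, *Bcs = U + 7 * npts,
                 *B42s = U + 8 * npts;
    double *rT = R, *rDm = R + npts, *rB42 = R + 2 * npts,
           *rBm = R + 3 * npts, *rDc = R + 4 * npts, *rBc = R + 5 * npts,
           *rBms = R + 6 * npts, *rBcs = R + 7 * npts, *rB42s = R + 8 * npts;
    for (int i = 0; i < npts; ++i) {
      double Bmt = Bm[i] + Bms[i];
      double Bct = Bc[i] + Bcs[i];
      double B42t = B42[i] + B42s[i];
      double k8 = hill(k8max, k8arg == 1 ? Bmt : B42t, k8n, k8h);
      double k9 = hill(k9max, k9arg == 1 ? Bms[i] : Bcs[i], k9n, k9h);
      double act = (k2a * Bm[i] + k3 * B42[i]) * Dm[i];
      double phos = k8 * B42t * B42[i];
      rT[i] = act - (k2b + k4a * Bmt + k7 * Bct) * T[i] + k4b * B42t;
      rDm[i] = k2b * T[i] - act - k5b * Dm[i] + k5a * Dc[i];
      rB42[i] = (k4a * Bm[i] + k7 * Bc[i]) * T[i] - k4b * B42[i] - phos;
      rBm[i] = k1a * Bc[i] - k1b * Bm[i] + k4b * B42[i] - k4a * Bm[i] * T[i];
      rDc[i] = eta * (k5b * Dm[i] - k5a * Dc[i]);
      rBc[i] = eta * (k1b * Bm[i] - k1a * Bc[i] - k7 * Bc[i] * T[i]) +
               k9 * Bcs[i];
      rBms[i] = k1a * Bcs[i] - k1b * Bms[i] + k4b * B42s[i] -
                k4a * Bms[i] * T[i];
      rBcs[i] = eta * (k1b * Bms[i] - k1a * Bcs[i] - k7 * Bcs[i] * T[i]) -
                k9 * Bcs[i];
      rB42s[i] = (k4a * Bms[i] + k7 * Bcs[i]) * T[i] - k4b * B42s[i] + phos;
    }
    break;
  }
  default:
    stop("unknown reaction kernel id");
  }
}

// [[Rcpp::export]]
NumericMatrix react_rates_cpp(NumericMatrix state, int kernel,
                              NumericVector params) {
  int npts = state.nrow(), ns = state.ncol();
  NumericMatrix out(npts, ns);
  react_all(kernel, params.begin(), state.begin(), out.begin(), npts, ns);
  return out;
}

// ---------------------------------------------------------------------------
// Main adaptive IMEX loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List imex_integrate_cpp(NumericMatrix state, int nx, int ny, double hx,
                        double hy, int bc, IntegerVector walls,
                        NumericVector D, int kernel, NumericVector params,
                        double t0, double t_end, NumericVector save_times,
                        double rtol, double dt_init, double dt_min,
                        double dt_max, double steady_tol, double max_steps,
                        double neg_tol) {
  const int npts = nx * ny, ns = state.ncol();
  if (state.nrow() != npts) stop("state rows do not match grid size");
  if ((int)D.size() != ns) stop("one diffusivity per species required");

  std::vector<char> wall_after;  // empty => no walls
  if (walls.size() > 0) {
    wall_after.assign(nx, 0);
    for (int k = 0; k < walls.size(); ++k) {
      int w = walls[k];
      if (w < 1 || w > nx) stop("wall interface outside the domain");
      wall_after[w - 1] = 1;
    }
  }
  std::vector<char> no_walls;

  std::vector<double> U(state.begin(), state.end());
  std::vector<double> Uprev(U), Uh((size_t)npts * ns),
      R1((size_t)npts * ns), R2((size_t)npts * ns);
  std::vector<double> scale(ns, 0.0);

  std::vector<TriSys> fx(ns), fy(ns);
  double fx_dt = -1.0, fy_dt = -1.0;

  const int nsave = save_times.size();
  std::vector<double> snaps((size_t)npts * ns * nsave);
  std::vector<double> snap_t(nsave);
  int isave = 0;

  double t = t0;
  double dt = std::min(std::max(dt_init, dt_min), dt_max);
  double maxrate = NA_REAL;
  double steps = 0, rejects = 0;
  bool steady = false;
  const double tiny = 1e-300;

  while (t < t_end - 1e-12 * std::max(1.0, std::fabs(t_end))) {
    double target = t_end;
    if (isave < nsave && save_times[isave] < target)
      target = save_times[isave];
    double dt_eff = std::min(dt, target - t);
    bool clipped = dt_eff < dt * 0.999999;
    double err = 0.0;
    bool accepted = false;

    while (!accepted) {
      // per-species scales
      for (int s = 0; s < ns; ++s) {
        double m = 0.0;
        const double* us = U.data() + (size_t)s * npts;
        for (int i = 0; i < npts; ++i) m = std::max(m, std::fabs(us[i]));
        scale[s] = std::max(m, tiny);
      }
      // explicit reaction with step-doubling error estimate
      react_all(kernel, params.begin(), U.data(), R1.data(), npts, ns);
      for (size_t k = 0; k < U.size(); ++k)
        Uh[k] = U[k] + 0.5 * dt_eff * R1[k];
      react_all(kernel, params.begin(), Uh.data(), R2.data(), npts, ns);
      err = 0.0;
      for (int s = 0; s < ns; ++s) {
        const size_t off = (size_t)s * npts;
        double esc = 1.0 / scale[s];
        for (int i = 0; i < npts; ++i) {
          size_t k = off + i;
          double i1 = dt_eff * R1[k];
          double i2 = 0.5 * dt_eff * (R1[k] + R2[k]);
          double e = std::fabs(i2 - i1) * esc;
          if (e > err) err = e;
          Uh[k] = U[k] + i2;
        }
      }
      if ((err > rtol || !std::isfinite(err)) && dt_eff > dt_min * 1.0000001) {
        dt = std::max(0.5 * dt_eff, dt_min);
        dt_eff = std::min(dt, target - t);
        clipped = dt_eff < dt * 0.999999;
        rejects += 1;
        if (rejects > max_steps)
          stop("step underflow: too many rejected steps at t = %g", t);
        continue;
      }

      // implicit diffusion sweeps on Uh
      if (dt_eff != fx_dt) {
        for (int s = 0; s < ns; ++s)
          fx[s].build(nx, dt_eff * D[s] / (hx * hx), bc, wall_after);
        fx_dt = dt_eff;
      }
      for (int s = 0; s < ns; ++s) {
        if (D[s] == 0.0) continue;
        double* col = Uh.data() + (size_t)s * npts;
        for (int y = 0; y < ny; ++y) fx[s].solve(col + (size_t)y * nx, 1);
      }
      if (ny > 1) {
        if (dt_eff != fy_dt) {
          for (int s = 0; s < ns; ++s)
            fy[s].build(ny, dt_eff * D[s] / (hy * hy), bc, no_walls);
          fy_dt = dt_eff;
        }
        for (int s = 0; s < ns; ++s) {
          if (D[s] == 0.0) continue;
          double* col = Uh.data() + (size_t)s * npts;
          for (int x = 0; x < nx; ++x) fy[s].solve(col + x, nx);
        }
      }

      // validity: NaN or strong negativity triggers a retry at smaller dt
      bool bad = false;
      for (int s = 0; s < ns && !bad; ++s) {
        const double* us = Uh.data() + (size_t)s * npts;
        double floor_s = -neg_tol * scale[s];
        for (int i = 0; i < npts; ++i) {
          if (!std::isfinite(us[i]) || us[i] < floor_s) { bad = true; break; }
        }
      }
      if (bad) {
        if (dt_eff <= dt_min * 1.0000001)
          stop("solution lost positivity/finiteness at t = %g with dt at dt_min",
               t);
        dt = std::max(0.5 * dt_eff, dt_min);
        dt_eff = std::min(dt, target - t);
        clipped = dt_eff < dt * 0.999999;
        rejects += 1;
        continue;
      }
      accepted = true;
    }

    Uprev.swap(U);
    U.swap(Uh);  // U now holds the accepted state; Uprev the previous one
    t += dt_eff;
    steps += 1;
    if (steps > max_steps)
      stop("maximum number of time steps exceeded at t = %g", t);

    // rate of change (diffusion + reaction), relative to field scale
    maxrate = 0.0;
    for (int s = 0; s < ns; ++s) {
      const size_t off = (size_t)s * npts;
      double m = 0.0;
      for (int i = 0; i < npts; ++i)
        m = std::max(m, std::fabs(U[off + i] - Uprev[off + i]));
      maxrate = std::max(maxrate, m / (dt_eff * scale[s]));
    }
    if (steady_tol > 0 && maxrate < steady_tol) steady = true;

    if (isave < nsave &&
        t >= save_times[isave] - 1e-9 * std::max(1.0, std::fabs(t))) {
      std::memcpy(snaps.data() + (size_t)isave * npts * ns, U.data(),
                  sizeof(double) * (size_t)npts * ns);
      snap_t[isave] = t;
      ++isave;
    }
    if (steady) break;

    // step-size adaptation: halve on rejection (above), double with margin
    if (err < rtol / 6.0)
      dt = std::max(dt, std::min(dt_eff * 2.0, dt_max));
    else if (!clipped)
      dt = dt_eff;
    dt = std::min(std::max(dt, dt_min), dt_max);
    if (steps + rejects > max_steps)
      stop("maximum number of time steps exceeded at t = %g", t);
  }

  NumericMatrix final_state(npts, ns);
  std::copy(U.begin(), U.end(), final_state.begin());

  NumericVector snap_out((size_t)npts * ns * isave);
  std::copy(snaps.begin(), snaps.begin() + (size_t)npts * ns * isave,
            snap_out.begin());
  snap_out.attr("dim") = IntegerVector::create(npts, ns, isave);

  return List::create(
      _["t"] = t, _["state"] = final_state, _["steady"] = steady,
      _["maxrate"] = maxrate, _["nsteps"] = steps, _["nrejects"] = rejects,
      _["dt_last"] = dt, _["times"] = NumericVector(snap_t.begin(),
                                                    snap_t.begin() + isave),
      _["snapshots"] = snap_out);
}
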