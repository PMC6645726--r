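// Compiled numerical core: adaptive RK45 (Cash-Karp) integration of the
// connectionist gap gene ODEs for many independent nuclei, and a multi-seed
// Newton-Raphson root finder for frozen (autonomous) vector fields.
//
// Model, per nucleus i and gene a:
//   dg_a/dt = R_a * phi(u_a) - lambda_a * g_a        (interphase)
//   dg_a/dt =             - lambda_a * g_a           (mitosis: production off)
//   u_a = sum_b W(b,a) g_b + sum_m E(m,a) m_m(t) + h_a
//   phi(u) = (u / sqrt(u^2 + 1) + 1) / 2
//
// W is stored regulator-by-target: W(b,a) = effect of regulator b on target a.
// Maternal inputs m_m(t) are piecewise linear in time on a shared knot grid,
// with one value series per nucleus (nuclei at different positions see
// different maternal concentrations).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double phi_sig(double u) {
  return 0.5 * (u / std::sqrt(u * u + 1.0) + 1.0);
}

static inline double phi_sig_deriv(double u) {
  double s = u * u + 1.0;
  return 0.5 / (s * std::sqrt(s));
}

// Linear interpolation of maternal values at time t for one nucleus.
// knots: length n_k (sorted ascending); vals: n_m x n_k slab for this nucleus.
// t is clamped to the knot span (callers validate coverage at the R level).
static void maternal_at(const double* knots, int n_k, const double* vals,
                        int n_m, double t, double* out) {
  if (n_k == 1) {
    for (int m = 0; m < n_m; ++m) out[m] = vals[m];
    return;
  }
  if (t <= knots[0]) {
    for (int m = 0; m < n_m; ++m) out[m] = vals[m];
    return;
  }
  if (t >= knots[n_k - 1]) {
    for (int m = 0; m < n_m; ++m) out[m] = vals[m + n_m * (n_k - 1)];
    return;
  }
  int lo = 0, hi = n_k - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (knots[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - knots[lo]) / (knots[hi] - knots[lo]);
  for (int m = 0; m < n_m; ++m) {
    double v0 = vals[m + n_m * lo], v1 = vals[m + n_m * hi];
    out[m] = v0 + w * (v1 - v0);
  }
}

struct CircuitPars {
  int n_g, n_m;
  const double *R, *lambda, *h, *W, *E;  // W: n_g x n_g, E: n_m x n_g (col-major)
};

static void rhs(const CircuitPars& p, const double* g, const double* mval,
                bool production, double* dg) {
  for (int a = 0; a < p.n_g; ++a) {
    double u = p.h[a];
    for (int b = 0; b < p.n_g; ++b) u += p.W[b + p.n_g * a] * g[b];
    for (int m = 0; m < p.n_m; ++m) u += p.E[m + p.n_m * a] * mval[m];
    double prod = production ? p.R[a] * phi_sig(u) : 0.0;
    dg[a] = prod - p.lambda[a] * g[a];
  }
}

// Cash-Karp tableau
static const double CK_C[6] = {0.0, 1.0 / 5, 3.0 / 10, 3.0 / 5, 1.0, 7.0 / 8};
static const double CK_A[6][5] = {
    {0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0},
    {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
    {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
    {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
     253.0 / 4096}};
static const double CK_B5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                                512.0 / 1771};
static const double CK_B4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 1.0 / 4};

// Integrate one nucleus from t0 to t1 writing snapshots at out_times
// (assumed sorted, inside [t0, t1]). g is modified in place.
// Returns last valid time on failure via *fail_t (NaN when successful).
static void integrate_one(const CircuitPars& p, std::vector<double>& g,
                          double t0, double t1, const double* out_times,
                          int n_out, bool production, const double* knots,
                          int n_k, const double* vals, double rtol, double atol,
                          double* out_states, int out_stride, double* fail_t) {
  const int n = p.n_g;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n);
  std::vector<double> ytmp(n), y5(n), y4(n), mval(p.n_m > 0 ? p.n_m : 1);
  std::vector<double>* ks[6] = {&k1, &k2, &k3, &k4, &k5, &k6};

  *fail_t = std::numeric_limits<double>::quiet_NaN();
  double t = t0;
  int iout = 0;
  // snapshots exactly at t0
  while (iout < n_out && out_times[iout] <= t0 + 1e-12 * std::max(1.0, std::fabs(t0))) {
    for (int a = 0; a < n; ++a) out_states[a + out_stride * iout] = g[a];
    ++iout;
  }
  if (t1 <= t0) return;

  double hstep = (t1 - t0) / 50.0;
  const double hmin = 1e-12 * std::max(1.0, t1 - t0);
  int nstep = 0, max_steps = 2000000;

  while (t < t1 - 1e-12 * std::max(1.0, std::fabs(t1))) {
    if (++nstep > max_steps) { *fail_t = t; return; }
    double tstop = t1;
    if (iout < n_out && out_times[iout] < tstop) tstop = out_times[iout];
    if (t + hstep > tstop) hstep = tstop - t;
    if (hstep < hmin) hstep = hmin;

    // stages
    maternal_at(knots, n_k, vals, p.n_m, t, mval.data());
    rhs(p, g.data(), mval.data(), production, k1.data());
    for (int s = 1; s < 6; ++s) {
      for (int a = 0; a < n; ++a) {
        double acc = g[a];
        for (int j = 0; j < s; ++j) acc += hstep * CK_A[s][j] * (*ks[j])[a];
        ytmp[a] = acc;
      }
      double ts = t + CK_C[s] * hstep;
      maternal_at(knots, n_k, vals, p.n_m, ts, mval.data());
      rhs(p, ytmp.data(), mval.data(), production, ks[s]->data());
    }
    double errmax = 0.0;
    for (int a = 0; a < n; ++a) {
      double s5 = 0.0, s4 = 0.0;
      for (int s = 0; s < 6; ++s) {
        s5 += CK_B5[s] * (*ks[s])[a];
        s4 += CK_B4[s] * (*ks[s])[a];
      }
      y5[a] = g[a] + hstep * s5;
      y4[a] = g[a] + hstep * s4;
      double sc = atol + rtol * std::max(std::fabs(g[a]), std::fabs(y5[a]));
      double e = std::fabs(y5[a] - y4[a]) / sc;
      if (e > errmax) errmax = e;
    }
    bool finite = true;
    for (int a = 0; a < n; ++a)
      if (!std::isfinite(y5[a])) finite = false;
    if (!finite) { *fail_t = t; return; }

    if (errmax <= 1.0 || hstep <= hmin * 1.000001) {
      // accept
      t += hstep;
      for (int a = 0; a < n; ++a) g[a] = y5[a];
      while (iout < n_out &&
             out_times[iout] <= t + 1e-12 * std::max(1.0, std::fabs(t))) {
        for (int a = 0; a < n; ++a) out_states[a + out_stride * iout] = g[a];
        ++iout;
      }
      double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      hstep *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      hstep *= fac;
    }
  }
  // safety: fill any snapshots numerically equal to t1
  while (iout < n_out) {
    for (int a = 0; a < n; ++a) out_states[a + out_stride * iout] = g[a];
    ++iout;
  }
}

// [[Rcpp::export]]
List cpp_integrate_nuclei(NumericMatrix g0, double t0, double t1,
                          NumericVector out_times, bool production,
                          NumericVector R, NumericVector lambda,
                          NumericVector h, NumericMatrix W, NumericMatrix E,
                          NumericVector mat_knots, NumericVector mat_vals,
                          double rtol, double atol) {
  const int n_g = g0.nrow();
  const int n_nuc = g0.ncol();
  const int n_m = E.nrow();
  const int n_k = mat_knots.size();
  const int n_out = out_times.size();

  if ((int)R.size() != n_g || (int)lambda.size() != n_g ||
      (int)h.size() != n_g || W.nrow() != n_g || W.ncol() != n_g ||
      E.ncol() != n_g)
    stop("parameter dimensions inconsistent with number of genes");
  if (n_m > 0 && (int)mat_vals.size() != n_m * n_k * n_nuc)
    stop("maternal value array has wrong length");

  CircuitPars p;
  p.n_g = n_g;
  p.n_m = n_m;
  p.R = R.begin();
  p.lambda = lambda.begin();
  p.h = h.begin();
  p.W = W.begin();
  p.E = E.begin();

  NumericVector states((R_xlen_t)n_g * n_nuc * n_out);
  NumericMatrix final_state(n_g, n_nuc);
  std::vector<double> out_buf(n_g * std::max(n_out, 1));
  std::vector<double> g(n_g);
  const double dummy_knot = 0.0, dummy_val = 0.0;

  for (int i = 0; i < n_nuc; ++i) {
    for (int a = 0; a < n_g; ++a) g[a] = g0(a, i);
    const double* vals =
        (n_m > 0) ? (mat_vals.begin() + (R_xlen_t)n_m * n_k * i) : &dummy_val;
    const double* knots = (n_m > 0 && n_k > 0) ? mat_knots.begin() : &dummy_knot;
    double fail_t;
    integrate_one(p, g, t0, t1, out_times.begin(), n_out, production, knots,
                  (n_m > 0) ? std::max(n_k, 1) : 1, vals, rtol, atol,
                  out_buf.data(), n_g, &fail_t);
    if (std::isfinite(fail_t))
      stop("ODE solver failure in nucleus column %d; last valid time %.6f min",
           i + 1, fail_t);
    for (int j = 0; j < n_out; ++j)
      for (int a = 0; a < n_g; ++a)
        states[a + n_g * (i + n_nuc * (R_xlen_t)j)] = out_buf[a + n_g * j];
    for (int a = 0; a < n_g; ++a) final_state(a, i) = g[a];
  }

  states.attr("dim") = IntegerVector::create(n_g, n_nuc, n_out);
  return List::create(_["states"] = states, _["final"] = final_state);
}

// Solve J x = b in place by Gaussian elimination with partial pivoting.
// Returns false if (numerically) singular.
static bool solve_small(std::vector<double>& J, std::vector<double>& b, int n) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(J[c + n * c]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::fabs(J[r + n * c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-14) return false;
    if (piv != c) {
      for (int k = 0; k < n; ++k) std::swap(J[c + n * k], J[piv + n * k]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c + 1; r < n; ++r) {
      double f = J[r + n * c] / J[c + n * c];
      if (f == 0.0) continue;
      for (int k = c; k < n; ++k) J[r + n * k] -= f * J[c + n * k];
      b[r] -= f * b[c];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double acc = b[c];
    for (int k = c + 1; k < n; ++k) acc -= J[c + n * k] * b[k];
    b[c] = acc / J[c + n * c];
  }
  return true;
}

// Newton-Raphson on the frozen field f_a(g) = R_a phi(u_a) - lambda_a g_a with
// u_a = sum_b W(b,a) g_b + heff_a (maternal contribution folded into heff).
// One run per seed column; returns roots, convergence flags, and residuals.
// [[Rcpp::export]]
List cpp_newton_census(NumericMatrix seeds, NumericVector R,
                       NumericVector lambda, NumericVector heff,
                       NumericMatrix W, double tol, int maxit) {
  const int n = seeds.nrow();
  const int n_s = seeds.ncol();
  if ((int)R.size() != n || (int)lambda.size() != n || (int)heff.size() != n ||
      W.nrow() != n || W.ncol() != n)
    stop("parameter dimensions inconsistent with seed dimension");

  NumericMatrix roots(n, n_s);
  LogicalVector converged(n_s);
  NumericVector resid(n_s);

  std::vector<double> g(n), u(n), f(n), J(n * n), step(n);
  for (int s = 0; s < n_s; ++s) {
    for (int a = 0; a < n; ++a) g[a] = seeds(a, s);
    bool ok = false;
    double rnorm = R_PosInf;
    for (int it = 0; it < maxit; ++it) {
      rnorm = 0.0;
      for (int a = 0; a < n; ++a) {
        double ua = heff[a];
        for (int b = 0; b < n; ++b) ua += W[b + n * a] * g[b];
        u[a] = ua;
        f[a] = R[a] * phi_sig(ua) - lambda[a] * g[a];
        double af = std::fabs(f[a]);
        if (af > rnorm) rnorm = af;
      }
      if (rnorm < tol) { ok = true; break; }
      for (int a = 0; a < n; ++a) {
        double dp = R[a] * phi_sig_deriv(u[a]);
        for (int b = 0; b < n; ++b)
          J[a + n * b] = dp * W[b + n * a] - (a == b ? lambda[a] : 0.0);
      }
      for (int a = 0; a < n; ++a) step[a] = -f[a];
      if (!solve_small(J, step, n)) break;
      bool finite = true;
      double gmax = 0.0;
      for (int a = 0; a < n; ++a) {
        g[a] += step[a];
        if (!std::isfinite(g[a])) finite = false;
        if (std::fabs(g[a]) > gmax) gmax = std::fabs(g[a]);
      }
      if (!finite || gmax > 1e10) break;
    }
    if (!ok) {
      // residual at the point where iteration stopped
      rnorm = 0.0;
      for (int a = 0; a < n; ++a) {
        double ua = heff[a];
        for (int b = 0; b < n; ++b) ua += W[b + n * a] * g[b];
        double fa = R[a] * phi_sig(ua) - lambda[a] * g[a];
        if (std::isfinite(fa)) {
          if (std::fabs(fa) > rnorm) rnorm = std::fabs(fa);
        } else
          rnorm = R_PosInf;
      }
      ok = rnorm < tol;
    }
    for (int a = 0; a < n; ++a) roots(a, s) = g[a];
    converged[s] = ok;
    resid[s] = rnorm;
  }
  return List::create(_["roots"] = roots, _["converged"] = converged,
                      _["resid"] = resid);
}
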