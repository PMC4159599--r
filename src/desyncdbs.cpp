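// Compiled numerical core: thalamic-cell vector field, adaptive Cash-Karp
// integration for the Euler-Lagrange shooting system, Fourier-series
// evaluation of orbit/PRC tabulations, driven-phase quadrature, the
// fixed-step stochastic Heun network integrator (circuit + event-based
// controller in the loop) and ballistic next-spike phase inference.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Reduced thalamocortical cell (leak, Na, K, low-threshold Ca T-current).
// Parameter vector layout: C, I_SM, gL, EL, gNa, ENa, gK, EK, gT, ET.
// Units: mV, ms, uA/cm^2, uF/cm^2.
// ---------------------------------------------------------------------------
struct ThalPar {
  double C, Ism, gL, EL, gNa, ENa, gK, EK, gT, ET;
};

static ThalPar as_thalpar(const NumericVector& p) {
  ThalPar q;
  q.C = p[0]; q.Ism = p[1]; q.gL = p[2]; q.EL = p[3]; q.gNa = p[4];
  q.ENa = p[5]; q.gK = p[6]; q.EK = p[7]; q.gT = p[8]; q.ET = p[9];
  return q;
}

static inline double f_minf(double v) { return 1.0 / (1.0 + exp(-(v + 37.0) / 7.0)); }
static inline double f_hinf(double v) { return 1.0 / (1.0 + exp((v + 41.0) / 4.0)); }
static inline double f_rinf(double v) { return 1.0 / (1.0 + exp((v + 84.0) / 4.0)); }
static inline double f_pinf(double v) { return 1.0 / (1.0 + exp(-(v + 60.0) / 6.2)); }
static inline double f_tauh(double v) {
  double ah = 0.128 * exp(-(v + 46.0) / 18.0);
  double bh = 4.0 / (1.0 + exp(-(v + 23.0) / 5.0));
  return 1.0 / (ah + bh);
}
static inline double f_taur(double v) { return 28.0 + exp(-(v + 25.0) / 10.5); }

// Total intrinsic membrane current I_m = -I_L - I_Na - I_K - I_T + I_SM
static inline double thal_im(const double* y, const ThalPar& p) {
  double V = y[0], h = y[1], r = y[2];
  double m = f_minf(V);
  double IL = p.gL * (V - p.EL);
  double INa = p.gNa * m * m * m * h * (V - p.ENa);
  double k4 = 0.75 * (1.0 - h);
  double IK = p.gK * k4 * k4 * k4 * k4 * (V - p.EK);
  double pi = f_pinf(V);
  double IT = p.gT * pi * pi * r * (V - p.ET);
  return -IL - INa - IK - IT + p.Ism;
}

static inline void thal_rhs(const double* y, double iapp, const ThalPar& p, double* dy) {
  double V = y[0], h = y[1], r = y[2];
  dy[0] = (thal_im(y, p) + iapp) / p.C;
  dy[1] = (f_hinf(V) - h) / f_tauh(V);
  dy[2] = (f_rinf(V) - r) / f_taur(V);
}

// [[Rcpp::export]]
NumericVector cpp_thal_im(NumericMatrix state, NumericVector par) {
  ThalPar p = as_thalpar(par);
  int n = state.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double y[3] = { state(i, 0), state(i, 1), state(i, 2) };
    out[i] = thal_im(y, p);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_thal_rhs(NumericMatrix state, NumericVector iapp, NumericVector par) {
  ThalPar p = as_thalpar(par);
  int n = state.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double y[3] = { state(i, 0), state(i, 1), state(i, 2) };
    double dy[3];
    thal_rhs(y, iapp[i % iapp.size()], p, dy);
    out(i, 0) = dy[0]; out(i, 1) = dy[1]; out(i, 2) = dy[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Truncated Fourier series on [0, 2pi): coef = (a0, a_1..a_K, b_1..b_K).
// ---------------------------------------------------------------------------
struct Four {
  int K;
  const double* a;  // a[0..K-1] cosine coefficients
  const double* b;  // b[0..K-1] sine coefficients
  double a0;
};

static Four as_four(const NumericVector& c) {
  Four F;
  F.K = (c.size() - 1) / 2;
  F.a0 = c[0];
  F.a = &c[1];
  F.b = &c[1 + F.K];
  return F;
}

static inline void four_eval(const Four& F, double th, double* v0, double* v1, double* v2) {
  double s0 = F.a0, s1 = 0.0, s2 = 0.0;
  double c1 = cos(th), s1t = sin(th);
  double ck = 1.0, sk = 0.0;  // cos(0), sin(0); advance by angle-addition
  for (int k = 1; k <= F.K; ++k) {
    double cn = ck * c1 - sk * s1t;
    double sn = sk * c1 + ck * s1t;
    ck = cn; sk = sn;  // now cos(k th), sin(k th)
    double ak = F.a[k - 1], bk = F.b[k - 1];
    s0 += ak * ck + bk * sk;
    s1 += k * (-ak * sk + bk * ck);
    s2 += (double)k * k * (-ak * ck - bk * sk);
  }
  if (v0) *v0 = s0;
  if (v1) *v1 = s1;
  if (v2) *v2 = s2;
}

// [[Rcpp::export]]
NumericMatrix cpp_fourier_eval(NumericVector coef, NumericVector theta) {
  Four F = as_four(coef);
  int n = theta.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double v0, v1, v2;
    four_eval(F, theta[i], &v0, &v1, &v2);
    out(i, 0) = v0; out(i, 1) = v1; out(i, 2) = v2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Adaptive Cash-Karp RK45 with output at prescribed times (step capped at
// the next output point; smooth systems only).
// ---------------------------------------------------------------------------
typedef void (*DerivFn)(double t, const double* y, double* dy, void* ctx);

static bool rkck(DerivFn fn, void* ctx, int n, double* y, double t0, double t1,
                 double rtol, double atol,
                 const double* tout, int nout, double* yout, double ycap) {
  const double b21 = 1.0 / 5.0;
  const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
               b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0;
  const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
               d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0, d6 = c6 - 0.25;

  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), yt(n), ynew(n);
  double t = t0;
  double h = (t1 - t0) / 100.0;
  int iout = 0;
  // emit any output points at/before t0
  while (iout < nout && tout[iout] <= t0 + 1e-14) {
    for (int j = 0; j < n; ++j) yout[iout + (size_t)nout * j] = y[j];
    ++iout;
  }
  int maxsteps = 2000000;
  for (int step = 0; step < maxsteps && t < t1 - 1e-14; ++step) {
    double hmax = t1 - t;
    if (iout < nout) hmax = std::min(hmax, tout[iout] - t);
    if (h > hmax) h = hmax;
    if (h < 1e-14) h = 1e-14;
    fn(t, y, k1.data(), ctx);
    for (int j = 0; j < n; ++j) yt[j] = y[j] + h * b21 * k1[j];
    fn(t + h / 5.0, yt.data(), k2.data(), ctx);
    for (int j = 0; j < n; ++j) yt[j] = y[j] + h * (b31 * k1[j] + b32 * k2[j]);
    fn(t + 3.0 * h / 10.0, yt.data(), k3.data(), ctx);
    for (int j = 0; j < n; ++j) yt[j] = y[j] + h * (b41 * k1[j] + b42 * k2[j] + b43 * k3[j]);
    fn(t + 3.0 * h / 5.0, yt.data(), k4.data(), ctx);
    for (int j = 0; j < n; ++j)
      yt[j] = y[j] + h * (b51 * k1[j] + b52 * k2[j] + b53 * k3[j] + b54 * k4[j]);
    fn(t + h, yt.data(), k5.data(), ctx);
    for (int j = 0; j < n; ++j)
      yt[j] = y[j] + h * (b61 * k1[j] + b62 * k2[j] + b63 * k3[j] + b64 * k4[j] + b65 * k5[j]);
    fn(t + 7.0 * h / 8.0, yt.data(), k6.data(), ctx);
    double errmax = 0.0;
    for (int j = 0; j < n; ++j) {
      ynew[j] = y[j] + h * (c1 * k1[j] + c3 * k3[j] + c4 * k4[j] + c6 * k6[j]);
      double err = h * (d1 * k1[j] + d3 * k3[j] + d4 * k4[j] + d5 * k5[j] + d6 * k6[j]);
      double sc = atol + rtol * std::max(fabs(y[j]), fabs(ynew[j]));
      errmax = std::max(errmax, fabs(err) / sc);
    }
    if (!std::isfinite(errmax)) return false;
    if (errmax <= 1.0) {
      t += h;
      for (int j = 0; j < n; ++j) y[j] = ynew[j];
      while (iout < nout && tout[iout] <= t + 1e-12) {
        for (int j = 0; j < n; ++j) yout[iout + (size_t)nout * j] = y[j];
        ++iout;
      }
      if (ycap > 0.0) {
        for (int j = 0; j < n; ++j)
          if (fabs(y[j]) > ycap) return false;  // blow-up guard for shooting
      }
      h *= std::min(5.0, 0.9 * pow(std::max(errmax, 1e-12), -0.2));
    } else {
      h *= std::max(0.1, 0.9 * pow(errmax, -0.25));
    }
  }
  return t >= t1 - 1e-10;
}

// ---------------------------------------------------------------------------
// Euler-Lagrange system for the optimal-stimulus boundary-value problem.
// State y = (X1=u_p, X2=du_p/dt, theta, u_e, lambda1, lambda2).
// par = (alpha, beta, gamma, sigma, omega, kct, ks) with kct = 1/(C_dl R_ct),
// ks = 1/(C_dl R_s), both in 1/ms.
// ---------------------------------------------------------------------------
struct ELCtx {
  double alpha, beta, gamma, sigma, omega, kct, ks;
  Four Z, f;
};

static void el_rhs_fn(double t, const double* y, double* dy, void* vctx) {
  (void)t;
  ELCtx* c = (ELCtx*)vctx;
  double X1 = y[0], X2 = y[1], th = y[2], ue = y[3], l1 = y[4], l2 = y[5];
  double Z, Zp, Zpp, fv, fp, fpp;
  four_eval(c->Z, th, &Z, &Zp, &Zpp);
  four_eval(c->f, th, &fv, &fp, &fpp);
  double r2 = 2.0 * c->gamma * (X1 - ue) - l1 * c->kct;
  double r3 = -(c->beta * Zpp + l2 * Zp) * ue;
  if (c->sigma != 0.0) r3 += c->beta * c->sigma * (fpp * Z + fp * Zp);
  double r4 = 2.0 * ue - c->beta * Zp - 2.0 * c->gamma * (X1 - ue) - l2 * Z +
              l1 * (c->kct + c->ks);
  dy[0] = X2;
  dy[1] = (r2 + r4) / (2.0 * c->alpha);
  dy[2] = c->omega + Z * ue;
  dy[3] = X2 + (X1 - ue) * c->kct - ue * c->ks;
  dy[4] = r4;
  dy[5] = r3;
}

// [[Rcpp::export]]
NumericMatrix cpp_el_rhs(NumericMatrix state, NumericVector par,
                         NumericVector zcoef, NumericVector fcoef) {
  ELCtx c;
  c.alpha = par[0]; c.beta = par[1]; c.gamma = par[2]; c.sigma = par[3];
  c.omega = par[4]; c.kct = par[5]; c.ks = par[6];
  c.Z = as_four(zcoef); c.f = as_four(fcoef);
  int n = state.nrow();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    double y[6], dy[6];
    for (int j = 0; j < 6; ++j) y[j] = state(i, j);
    el_rhs_fn(0.0, y, dy, &c);
    for (int j = 0; j < 6; ++j) out(i, j) = dy[j];
  }
  return out;
}

// Integrate the EL system from the stated zero initial conditions with trial
// multipliers (l1_0, l2_0); returns a (nout x 7) matrix (t, X1..lambda2), or
// a 1x1 NA matrix on blow-up.
// [[Rcpp::export]]
NumericMatrix cpp_el_integrate(double l1_0, double l2_0, NumericVector par,
                               NumericVector zcoef, NumericVector fcoef,
                               NumericVector tout, double rtol, double ycap) {
  ELCtx c;
  c.alpha = par[0]; c.beta = par[1]; c.gamma = par[2]; c.sigma = par[3];
  c.omega = par[4]; c.kct = par[5]; c.ks = par[6];
  c.Z = as_four(zcoef); c.f = as_four(fcoef);
  double y[6] = { 0.0, 0.0, 0.0, 0.0, l1_0, l2_0 };
  int nout = tout.size();
  std::vector<double> buf((size_t)nout * 6, NA_REAL);
  bool ok = rkck(el_rhs_fn, &c, 6, y, 0.0, tout[nout - 1], rtol, 1e-12,
                 &tout[0], nout, buf.data(), ycap);
  if (!ok) {
    NumericMatrix bad(1, 1);
    bad(0, 0) = NA_REAL;
    return bad;
  }
  NumericMatrix out(nout, 7);
  for (int i = 0; i < nout; ++i) {
    out(i, 0) = tout[i];
    for (int j = 0; j < 6; ++j) out(i, j + 1) = buf[i + (size_t)nout * j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Driven phase equation dtheta/dt = omega + Z(theta) u(t) with accumulated
// quadratures  int Z'(theta) u dt  and  int f'(theta) Z(theta) dt.
// u is sampled on a uniform grid (linear interpolation inside steps).
// ---------------------------------------------------------------------------
struct PhaseCtx {
  double omega;
  Four Z, f;
  const double* u;
  int nu;
  double dt;
};

static inline double u_at(const PhaseCtx* c, double t) {
  double x = t / c->dt;
  int i = (int)floor(x);
  if (i < 0) return c->u[0];
  if (i >= c->nu - 1) return c->u[c->nu - 1];
  double w = x - i;
  return (1.0 - w) * c->u[i] + w * c->u[i + 1];
}

static void phase_rhs_fn(double t, const double* y, double* dy, void* vctx) {
  PhaseCtx* c = (PhaseCtx*)vctx;
  double th = y[0];
  double Z, Zp, fv, fp;
  four_eval(c->Z, th, &Z, &Zp, NULL);
  four_eval(c->f, th, &fv, &fp, NULL);
  double u = u_at(c, t);
  dy[0] = c->omega + Z * u;
  dy[1] = Zp * u;
  dy[2] = fp * Z;
}

// [[Rcpp::export]]
List cpp_phase_quadrature(NumericVector u, double dt, double theta0, double omega,
                          NumericVector zcoef, NumericVector fcoef, double tau) {
  PhaseCtx c;
  c.omega = omega;
  c.Z = as_four(zcoef); c.f = as_four(fcoef);
  c.u = &u[0]; c.nu = u.size(); c.dt = dt;
  int nout = (int)round(tau / dt) + 1;
  NumericVector tout(nout);
  for (int i = 0; i < nout; ++i) tout[i] = std::min(i * dt, tau);
  double y[3] = { theta0, 0.0, 0.0 };
  std::vector<double> buf((size_t)nout * 3, NA_REAL);
  bool ok = rkck(phase_rhs_fn, &c, 3, y, 0.0, tau, 1e-10, 1e-12,
                 &tout[0], nout, buf.data(), -1.0);
  if (!ok) stop("phase integration failed");
  NumericVector theta(nout);
  for (int i = 0; i < nout; ++i) theta[i] = buf[i];
  return List::create(_["t"] = tout, _["theta"] = theta,
                      _["int_zpu"] = y[1], _["int_fpz"] = y[2]);
}

// Coupled phase ensemble (Eq.-13-type dynamics): theta_j' = omega + Z(theta_j) u
//   + (sigma/N) Z(theta_j) sum_i (f(theta_i) - f(theta_j)).
// Accumulates, for the reference oscillator (index 0), the exact coupled
// Lyapunov integrand  Z'(th)(u + (sigma/N) sum_i (f(th_i)-f(th))) - sigma f'(th)Z(th).
struct EnsCtx {
  double omega, sigma;
  Four Z, f;
  const double* u;
  int nu;
  double dt;
  int N;
};

static void ens_rhs_fn(double t, const double* y, double* dy, void* vctx) {
  EnsCtx* c = (EnsCtx*)vctx;
  int N = c->N;
  double u = 0.0;
  {
    double x = t / c->dt;
    int i = (int)floor(x);
    if (i < 0) u = c->u[0];
    else if (i >= c->nu - 1) u = c->u[c->nu - 1];
    else { double w = x - i; u = (1.0 - w) * c->u[i] + w * c->u[i + 1]; }
  }
  std::vector<double> fv(N), Zv(N), Zp0(1);
  double fsum = 0.0;
  double Zp_ref = 0.0, fp_ref = 0.0, Z_ref = 0.0;
  for (int j = 0; j < N; ++j) {
    double Z, Zp, f0, fp;
    four_eval(c->Z, y[j], &Z, &Zp, NULL);
    four_eval(c->f, y[j], &f0, &fp, NULL);
    fv[j] = f0; Zv[j] = Z;
    fsum += f0;
    if (j == 0) { Zp_ref = Zp; fp_ref = fp; Z_ref = Z; }
  }
  for (int j = 0; j < N; ++j) {
    double coup = c->sigma * (fsum / N - fv[j]);  // (sigma/N) sum_i (f_i - f_j)
    dy[j] = c->omega + Zv[j] * (u + coup);
  }
  double coup0 = c->sigma * (fsum / N - fv[0]);
  dy[N] = Zp_ref * (u + coup0) - c->sigma * fp_ref * Z_ref;
}

// [[Rcpp::export]]
List cpp_phase_ensemble(NumericVector theta0, NumericVector u, double dt,
                        double omega, double sigma,
                        NumericVector zcoef, NumericVector fcoef, double tau) {
  EnsCtx c;
  c.omega = omega; c.sigma = sigma;
  c.Z = as_four(zcoef); c.f = as_four(fcoef);
  c.u = &u[0]; c.nu = u.size(); c.dt = dt;
  c.N = theta0.size();
  int n = c.N + 1;
  std::vector<double> y(n, 0.0);
  for (int j = 0; j < c.N; ++j) y[j] = theta0[j];
  double tend = tau;
  NumericVector tout = NumericVector::create(tend);
  std::vector<double> buf((size_t)1 * n, NA_REAL);
  bool ok = rkck(ens_rhs_fn, &c, n, y.data(), 0.0, tend, 1e-9, 1e-12,
                 &tout[0], 1, buf.data(), -1.0);
  if (!ok) stop("ensemble phase integration failed");
  NumericVector thf(c.N);
  for (int j = 0; j < c.N; ++j) thf[j] = y[j];
  return List::create(_["theta_final"] = thf, _["integral"] = y[c.N]);
}

// ---------------------------------------------------------------------------
// Ballistic next-spike times: integrate each frozen state forward, input-free
// and noise-free, with fixed-step RK4 until V crosses vthresh upward.
// ---------------------------------------------------------------------------
static inline void rk4_thal(double* y, double dt, const ThalPar& p) {
  double k1[3], k2[3], k3[3], k4[3], yt[3];
  thal_rhs(y, 0.0, p, k1);
  for (int j = 0; j < 3; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
  thal_rhs(yt, 0.0, p, k2);
  for (int j = 0; j < 3; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
  thal_rhs(yt, 0.0, p, k3);
  for (int j = 0; j < 3; ++j) yt[j] = y[j] + dt * k3[j];
  thal_rhs(yt, 0.0, p, k4);
  for (int j = 0; j < 3; ++j)
    y[j] += dt * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]) / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_next_spike(NumericMatrix states, NumericVector par,
                             double vthresh, double dt, double horizon) {
  ThalPar p = as_thalpar(par);
  int n = states.nrow();
  NumericVector out(n, NA_REAL);
  int nmax = (int)ceil(horizon / dt);
  for (int i = 0; i < n; ++i) {
    double y[3] = { states(i, 0), states(i, 1), states(i, 2) };
    double vprev = y[0];
    bool below = vprev < vthresh;
    double t = 0.0;
    for (int s = 0; s < nmax; ++s) {
      rk4_thal(y, dt, p);
      t += dt;
      if (below && y[0] >= vthresh) {
        double frac = (vthresh - vprev) / (y[0] - vprev);
        out[i] = t - dt + frac * dt;
        break;
      }
      below = y[0] < vthresh;
      vprev = y[0];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Coupled noisy network with electrode circuit and event-based controller.
//
// dV_i = [I_m,i + C u_e s_i + sigma (Vbar - V_i) + eta_i]/C, eta ~ sqrt(2D) N(0,1)
// (all-to-all electrotonic coupling (1/N) sum_j sigma (V_j - V_i) with
// sigma_ii = 0 collapses to sigma (Vbar - V_i)).
//
// Drift by stochastic Heun (two-stage second-order Runge-Kutta), Gaussian
// increments sqrt(2D dt) applied to V only. The circuit state is advanced
// with the exact exponential update of the continuous variable w = u_e - u_p,
// which stays continuous across pulse edges: w' = -(kct+ks) w - ks u_p.
//
// mode: 0 = no stimulus, 1 = event-based playback of `stim`, 2 = continuous
// playback of `stim` from t = 0 (pulsatile baseline).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_network_sim(NumericMatrix init, NumericVector par, double dt, int nsteps,
                     double sigma, double D, NumericVector scale,
                     NumericVector stim, double stim_dt,
                     int mode, double kct, double ks,
                     double trig_thresh, double rearm_thresh, double lockout,
                     int rec_stride) {
  ThalPar p = as_thalpar(par);
  int N = init.nrow();
  std::vector<double> V(N), h(N), r(N);
  for (int i = 0; i < N; ++i) { V[i] = init(i, 0); h[i] = init(i, 1); r[i] = init(i, 2); }

  int nstim = stim.size();
  double stim_len = (nstim - 1) * stim_dt;
  double sq = sqrt(2.0 * D * dt);

  // circuit state
  double w = 0.0;
  double aa = kct + ks;
  double eAdt = exp(-aa * dt);
  double I0 = (1.0 - eAdt) / aa;
  double I1 = (dt - I0) / aa;

  // controller
  bool active = true, playing = (mode == 2);
  bool armed = true;           // one trigger per upward excursion
  double play_t = 0.0;         // time since playback start
  double last_end = -1e18;     // when the last stimulus finished
  double last_up_cross = 0.0;  // last upward crossing of trig_thresh
  std::vector<double> trig_times;

  int nrec = nsteps / rec_stride + 1;
  NumericMatrix Vrec(nrec, N), hrec(nrec, N), rrec(nrec, N);
  NumericVector t_rec(nrec);
  NumericVector vbar_tr(nsteps + 1), ue_tr(nsteps + 1), up_tr(nsteps + 1);

  std::vector<double> F1V(N), F1h(N), F1r(N), Vp(N), hp(N), rp(N), noise(N);

  double energy = 0.0, faradaic = 0.0;  // trapezoids accumulated at full res

  double vbar = 0.0;
  for (int i = 0; i < N; ++i) vbar += V[i];
  vbar /= N;
  double vbar_prev = vbar;

  auto up_of = [&](double t_now) -> double {
    if (mode == 0) return 0.0;
    double tp = (mode == 2) ? t_now : (playing ? play_t : -1.0);
    if (tp < 0.0 || tp > stim_len) return 0.0;
    double x = tp / stim_dt;
    int i = (int)floor(x);
    if (i >= nstim - 1) return stim[nstim - 1];
    double wgt = x - i;
    return (1.0 - wgt) * stim[i] + wgt * stim[i + 1];
  };

  double up_now = up_of(0.0);
  w = 0.0 - up_now;  // u_e(0) = 0
  double ue_now = w + up_now;

  vbar_tr[0] = vbar; ue_tr[0] = ue_now; up_tr[0] = up_now;
  t_rec[0] = 0.0;
  for (int i = 0; i < N; ++i) { Vrec(0, i) = V[i]; hrec(0, i) = h[i]; rrec(0, i) = r[i]; }
  int irec = 1;

  for (int s = 0; s < nsteps; ++s) {
    double t_now = s * dt;

    // ---- controller ----
    if (mode == 1) {
      bool up_cross = (vbar_prev <= trig_thresh && vbar > trig_thresh);
      if (up_cross) { last_up_cross = t_now; armed = true; }
      if (active && !playing && armed && vbar > trig_thresh && vbar < vbar_prev) {
        playing = true;
        play_t = 0.0;
        armed = false;
        trig_times.push_back(t_now);
      }
      if (active && !playing && t_now - last_end > lockout &&
          last_up_cross < last_end) {
        active = false;
      }
      if (!active && vbar > rearm_thresh) { active = true; armed = false; }
    }

    // ---- circuit over [t, t+dt] (exact exponential update of w) ----
    double up0 = up_of(t_now);  // re-evaluated: a trigger at t_now starts playback now
    if (mode == 1 && playing) play_t += dt;
    double up1 = up_of(t_now + dt);
    if (mode == 1 && playing && play_t >= stim_len) {
      playing = false;
      last_end = t_now + dt;
    }
    double w1 = eAdt * w - ks * (up0 * I0 + (up1 - up0) / dt * I1);
    double ue0 = w + up0;
    double ue1 = w1 + up1;

    // ---- stochastic Heun step on (V, h, r) ----
    for (int i = 0; i < N; ++i) noise[i] = (D > 0.0) ? sq * norm_rand() : 0.0;
    for (int i = 0; i < N; ++i) {
      double y[3] = { V[i], h[i], r[i] };
      double iapp = p.C * ue0 * scale[i] + sigma * (vbar - V[i]);
      double dy[3];
      thal_rhs(y, iapp, p, dy);
      F1V[i] = dy[0]; F1h[i] = dy[1]; F1r[i] = dy[2];
      Vp[i] = V[i] + dt * dy[0] + noise[i] / p.C;
      hp[i] = h[i] + dt * dy[1];
      rp[i] = r[i] + dt * dy[2];
    }
    double vbarp = 0.0;
    for (int i = 0; i < N; ++i) vbarp += Vp[i];
    vbarp /= N;
    for (int i = 0; i < N; ++i) {
      double y[3] = { Vp[i], hp[i], rp[i] };
      double iapp = p.C * ue1 * scale[i] + sigma * (vbarp - Vp[i]);
      double dy[3];
      thal_rhs(y, iapp, p, dy);
      V[i] += 0.5 * dt * (F1V[i] + dy[0]) + noise[i] / p.C;
      h[i] += 0.5 * dt * (F1h[i] + dy[1]);
      r[i] += 0.5 * dt * (F1r[i] + dy[2]);
      if (!std::isfinite(V[i]))
        stop("non-finite state at t = %f (neuron %d)", t_now, i + 1);
    }

    // ---- metrics / records ----
    energy += 0.5 * dt * (ue0 * ue0 + ue1 * ue1);
    faradaic += 0.5 * dt * (fabs(up0 - ue0) + fabs(up1 - ue1));

    w = w1;
    up_now = up1;
    ue_now = ue1;
    vbar_prev = vbar;
    vbar = 0.0;
    for (int i = 0; i < N; ++i) vbar += V[i];
    vbar /= N;

    vbar_tr[s + 1] = vbar; ue_tr[s + 1] = ue_now; up_tr[s + 1] = up_now;
    if ((s + 1) % rec_stride == 0 && irec < nrec) {
      t_rec[irec] = (s + 1) * dt;
      for (int i = 0; i < N; ++i) {
        Vrec(irec, i) = V[i]; hrec(irec, i) = h[i]; rrec(irec, i) = r[i];
      }
      ++irec;
    }
  }

  return List::create(
    _["t"] = t_rec, _["V"] = Vrec, _["h"] = hrec, _["r"] = rrec,
    _["vbar"] = vbar_tr, _["u_e"] = ue_tr, _["u_p"] = up_tr,
    _["energy"] = energy, _["faradaic_raw"] = faradaic,
    _["triggers"] = wrap(trig_times));
}

// Integrate the (autonomous) Euler-Lagrange system from an arbitrary state
// for a given duration; used by the multiple-shooting corrector.
// [[Rcpp::export]]
NumericVector cpp_el_from(NumericVector y0, NumericVector par,
                          NumericVector zcoef, NumericVector fcoef,
                          double tlen, double rtol, double ycap) {
  ELCtx c;
  c.alpha = par[0]; c.beta = par[1]; c.gamma = par[2]; c.sigma = par[3];
  c.omega = par[4]; c.kct = par[5]; c.ks = par[6];
  c.Z = as_four(zcoef); c.f = as_four(fcoef);
  double y[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  double tout = tlen;
  std::vector<double> buf(6, NA_REAL);
  bool ok = rkck(el_rhs_fn, &c, 6, y, 0.0, tlen, rtol, 1e-12, &tout, 1, buf.data(), ycap);
  NumericVector out(6, NA_REAL);
  if (ok) for (int j = 0; j < 6; ++j) out[j] = y[j];
  return out;
}

// ---------------------------------------------------------------------------
// Direct transcription of the design cost on a uniform grid with an
// analytic discrete adjoint: probe samples u_p -> circuit (exact
// exponential update of w = u_e - u_p) -> driven phase (Heun) -> cost
//   J = sum w_k [u_e^2 - beta Z'(theta) u_e + gamma (u_p - u_e)^2
//                + beta*sigma f'(theta) Z(theta)]
//       + alpha sum (du_p)^2 dt + mu u_e(t1)^2,
// and its exact gradient with respect to every u_p sample.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_direct_cost_grad(NumericVector up, NumericVector par,
                          NumericVector zcoef, NumericVector fcoef,
                          double dt, double mu) {
  double alpha = par[0], beta = par[1], gamma = par[2], sigma = par[3],
         omega = par[4], kct = par[5], ks = par[6];
  Four Z4 = as_four(zcoef), F4 = as_four(fcoef);
  int n = up.size();
  double a = kct + ks;
  double E = exp(-a * dt);
  double I0 = (1.0 - E) / a, I1 = (dt - I0) / a;
  double c0 = -ks * (I0 - I1 / dt), c1 = -ks * I1 / dt;

  std::vector<double> w(n), ue(n), th(n), Z(n), zp(n), zpp(n), fp(n), fpp(n), fv(n);
  w[0] = -up[0];
  for (int k = 0; k < n - 1; ++k) w[k + 1] = E * w[k] + c0 * up[k] + c1 * up[k + 1];
  for (int k = 0; k < n; ++k) ue[k] = w[k] + up[k];
  th[0] = 0.0;
  std::vector<double> thm(n), Zm(n), Zmp(n);
  for (int k = 0; k < n; ++k) {
    if (k > 0) {
      double p = omega + Z[k - 1] * ue[k - 1];
      thm[k - 1] = th[k - 1] + dt * p;
      double z0, z1;
      four_eval(Z4, thm[k - 1], &z0, &z1, NULL);
      Zm[k - 1] = z0; Zmp[k - 1] = z1;
      th[k] = th[k - 1] + 0.5 * dt * (p + omega + z0 * ue[k]);
    }
    double v0, v1, v2;
    four_eval(Z4, th[k], &v0, &v1, &v2);
    Z[k] = v0; zp[k] = v1; zpp[k] = v2;
    four_eval(F4, th[k], &v0, &v1, &v2);
    fv[k] = v0; fp[k] = v1; fpp[k] = v2;
  }
  double J = 0.0;
  std::vector<double> wq(n, dt);
  wq[0] = wq[n - 1] = dt / 2.0;
  for (int k = 0; k < n; ++k) {
    J += wq[k] * (ue[k] * ue[k] - beta * zp[k] * ue[k] +
                  gamma * (up[k] - ue[k]) * (up[k] - ue[k]) +
                  beta * sigma * fp[k] * Z[k]);
  }
  for (int k = 0; k < n - 1; ++k) {
    double d = (up[k + 1] - up[k]) / dt;
    J += alpha * d * d * dt;
  }
  J += mu * ue[n - 1] * ue[n - 1];

  // ---- reverse sweep ----
  std::vector<double> ue_b(n), th_b_dir(n), up_b(n, 0.0), wb(n);
  for (int k = 0; k < n; ++k) {
    ue_b[k] = wq[k] * (2.0 * ue[k] - beta * zp[k] - 2.0 * gamma * (up[k] - ue[k]));
    th_b_dir[k] = wq[k] * (-beta * zpp[k] * ue[k] +
                           beta * sigma * (fpp[k] * Z[k] + fp[k] * zp[k]));
  }
  ue_b[n - 1] += 2.0 * mu * ue[n - 1];
  double tb = th_b_dir[n - 1];
  for (int k = n - 2; k >= 0; --k) {
    double gthk = zp[k] * ue[k];
    double dth_dthk = 1.0 + 0.5 * dt * (gthk + Zmp[k] * ue[k + 1] * (1.0 + dt * gthk));
    double dth_duek = 0.5 * dt * (Z[k] + Zmp[k] * ue[k + 1] * dt * Z[k]);
    double dth_duek1 = 0.5 * dt * Zm[k];
    ue_b[k] += tb * dth_duek;
    ue_b[k + 1] += tb * dth_duek1;
    tb = th_b_dir[k] + tb * dth_dthk;
  }
  for (int k = 0; k < n; ++k) up_b[k] = ue_b[k] + wq[k] * 2.0 * gamma * (up[k] - ue[k]);
  // slew
  for (int k = 0; k < n - 1; ++k) {
    double d = 2.0 * alpha * (up[k + 1] - up[k]) / dt;
    up_b[k] -= d;
    up_b[k + 1] += d;
  }
  wb[n - 1] = ue_b[n - 1];
  for (int k = n - 2; k >= 0; --k) wb[k] = ue_b[k] + E * wb[k + 1];
  for (int k = 0; k < n - 1; ++k) {
    up_b[k] += c0 * wb[k + 1];
    up_b[k + 1] += c1 * wb[k + 1];
  }
  up_b[0] -= wb[0];
  return List::create(_["J"] = J, _["grad"] = wrap(up_b));
}
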