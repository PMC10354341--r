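#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time LTI state stepping: x[k+1] = A x[k] + B u[k], y[k] = C x[k] + D u[k].
// U is T x m (one column per input channel). Returns Y (T x p).
// [[Rcpp::export]]
NumericMatrix dlti_sim_cpp(const NumericMatrix& A, const NumericMatrix& B,
                           const NumericMatrix& C, const NumericMatrix& D,
                           const NumericMatrix& U, const NumericVector& x0) {
  const int n = A.nrow(), m = B.ncol(), p = C.nrow(), T = U.nrow();
  if (U.ncol() != m) stop("input matrix has %d columns, system has %d inputs", U.ncol(), m);
  std::vector<double> x(x0.begin(), x0.end()), xn(n);
  NumericMatrix Y(T, p);
  for (int k = 0; k < T; ++k) {
    for (int i = 0; i < p; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += C(i, j) * x[j];
      for (int j = 0; j < m; ++j) acc += D(i, j) * U(k, j);
      Y(k, i) = acc;
    }
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += A(i, j) * x[j];
      for (int j = 0; j < m; ++j) acc += B(i, j) * U(k, j);
      xn[i] = acc;
    }
    x.swap(xn);
  }
  return Y;
}

// Stand-in cortico-thalamic neural mass: seven populations
// x = (v, w, Ve, Vi, Vte, Vti, Vret) with tanh rate coupling and a
// conduction delay tau on all cortico-thalamic and thalamo-cortical fibers.
//
//   tau_j dx_j/dt = -x_j + tanh(sum of weighted presynaptic activity)
//
// Exogenous input (stimulation scaled by Bvec and additive noise, both
// piecewise constant over a step) is added to dx/dt outside the sigmoid at
// every integration stage, so the constant-over-step input response is
// integrated with full RK4 accuracy.
// Integration: classical RK4 with fixed step dt; the delayed state is read
// from a history ring buffer with linear interpolation at half steps.
struct CTPar {
  double tau_v, tau_w, tau_e, tau_i, tau_t, tau_r, delay;
  double n_vv, n_vw, n_vt;            // superficial cortex (gamma pair)
  double n_wv, n_ww;
  double n_ee, n_ei, n_et, n_ev;      // deep cortex
  double n_ie;
  double n_te, n_tr, n_ti;            // thalamic relay
  double n_it;                        // relay interneurons
  double n_re, n_rt;                  // reticular
};

static inline void ct_deriv(const CTPar& P, const double* x, const double* xd,
                            const double* exo, double* dx) {
  dx[0] = (-x[0] + std::tanh(P.n_vv * x[0] - P.n_vw * x[1] + P.n_vt * xd[4])) / P.tau_v + exo[0];
  dx[1] = (-x[1] + std::tanh(P.n_wv * x[0] - P.n_ww * x[1])) / P.tau_w + exo[1];
  dx[2] = (-x[2] + std::tanh(P.n_ee * x[2] - P.n_ei * x[3] + P.n_et * xd[4] + P.n_ev * x[0])) / P.tau_e + exo[2];
  dx[3] = (-x[3] + std::tanh(P.n_ie * x[2])) / P.tau_i + exo[3];
  dx[4] = (-x[4] + std::tanh(P.n_te * xd[2] - P.n_tr * xd[6] - P.n_ti * x[5])) / P.tau_t + exo[4];
  dx[5] = (-x[5] + std::tanh(P.n_it * x[6])) / P.tau_t + exo[5];
  dx[6] = (-x[6] + std::tanh(P.n_re * xd[2] + P.n_rt * x[4])) / P.tau_r + exo[6];
}

// pars: named numeric vector with the CTPar fields.
// U: T x 1 stimulation (already at the simulation rate), may have 0 rows for no input.
// Bvec: length-7 input coupling column. Noise: T x 7 matrix of per-step
// additive noise increments (interpreted as constant over each step, added
// to dx/dt). x0: initial state, held constant on [-delay, 0].
// [[Rcpp::export]]
NumericMatrix ct_sim_cpp(const NumericVector& pars, const NumericMatrix& U,
                         const NumericVector& Bvec, const NumericMatrix& Noise,
                         const NumericVector& x0, double dt, int T) {
  CTPar P;
  P.tau_v = pars["tau_v"]; P.tau_w = pars["tau_w"]; P.tau_e = pars["tau_e"];
  P.tau_i = pars["tau_i"]; P.tau_t = pars["tau_t"]; P.tau_r = pars["tau_r"];
  P.delay = pars["delay"];
  P.n_vv = pars["n_vv"]; P.n_vw = pars["n_vw"]; P.n_vt = pars["n_vt"];
  P.n_wv = pars["n_wv"]; P.n_ww = pars["n_ww"];
  P.n_ee = pars["n_ee"]; P.n_ei = pars["n_ei"]; P.n_et = pars["n_et"]; P.n_ev = pars["n_ev"];
  P.n_ie = pars["n_ie"];
  P.n_te = pars["n_te"]; P.n_tr = pars["n_tr"]; P.n_ti = pars["n_ti"];
  P.n_it = pars["n_it"];
  P.n_re = pars["n_re"]; P.n_rt = pars["n_rt"];

  const int n = 7;
  const int dlag = (int)std::lround(P.delay / dt);
  if (dlag < 0) stop("negative delay");
  const bool have_u = U.nrow() > 0;
  const bool have_noise = Noise.nrow() > 0;

  // history buffer: states at integer steps, index k stores x(k*dt)
  const int H = dlag + 2;
  std::vector<double> hist((size_t)H * n);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < n; ++i) hist[(size_t)j * n + i] = x0[i];

  NumericMatrix X(T, n);
  std::vector<double> x(x0.begin(), x0.end());
  double k1[7], k2[7], k3[7], k4[7], xt[7], xda[7], xdb[7], xdm[7];

  for (int k = 0; k < T; ++k) {
    // delayed states: x(t - delay) and x(t + dt - delay), midpoint by interpolation
    auto read_hist = [&](int step, double* out) {
      int idx = ((step % H) + H) % H;
      const double* src = &hist[(size_t)idx * n];
      for (int i = 0; i < n; ++i) out[i] = src[i];
    };
    if (dlag == 0) {
      // delayed state equals current within a step; use current value throughout
      for (int i = 0; i < n; ++i) { xda[i] = x[i]; xdb[i] = x[i]; xdm[i] = x[i]; }
    } else {
      read_hist(k - dlag, xda);
      read_hist(k - dlag + 1, xdb);
      for (int i = 0; i < n; ++i) xdm[i] = 0.5 * (xda[i] + xdb[i]);
    }
    double uk = have_u ? U(k, 0) : 0.0;
    double exo[7];
    for (int i = 0; i < n; ++i)
      exo[i] = Bvec[i] * uk + (have_noise ? Noise(k, i) : 0.0);

    ct_deriv(P, x.data(), xda, exo, k1);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    ct_deriv(P, xt, xdm, exo, k2);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    ct_deriv(P, xt, xdm, exo, k3);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * k3[i];
    ct_deriv(P, xt, xdb, exo, k4);

    for (int i = 0; i < n; ++i) {
      double drift = (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]) / 6.0;
      x[i] += dt * drift;
      if (!std::isfinite(x[i]))
        stop("state diverged (non-finite) at t = %.3f s", k * dt);
      X(k, i) = x[i];
    }
    // store x((k+1) dt)
    int idx = ((k + 1) % H + H) % H;
    for (int i = 0; i < n; ++i) hist[(size_t)idx * n + i] = x[i];
  }
  return X;
}

// Closed-loop co-simulation: nonlinear cortico-thalamic plant + discrete LTI
// controller (y -> u) + integer-step input delay chain. Returns columns
// (y, u).
// [[Rcpp::export]]
NumericMatrix ct_closed_loop_cpp(const NumericVector& pars,
                                 const NumericVector& Bvec,
                                 const NumericVector& Cobs,
                                 const NumericMatrix& Noise,
                                 const NumericVector& x0, double dt, int T,
                                 const NumericMatrix& Ac,
                                 const NumericMatrix& Bc,
                                 const NumericMatrix& Cc,
                                 const NumericMatrix& Dc, int delay_steps) {
  CTPar P;
  P.tau_v = pars["tau_v"]; P.tau_w = pars["tau_w"]; P.tau_e = pars["tau_e"];
  P.tau_i = pars["tau_i"]; P.tau_t = pars["tau_t"]; P.tau_r = pars["tau_r"];
  P.delay = pars["delay"];
  P.n_vv = pars["n_vv"]; P.n_vw = pars["n_vw"]; P.n_vt = pars["n_vt"];
  P.n_wv = pars["n_wv"]; P.n_ww = pars["n_ww"];
  P.n_ee = pars["n_ee"]; P.n_ei = pars["n_ei"]; P.n_et = pars["n_et"]; P.n_ev = pars["n_ev"];
  P.n_ie = pars["n_ie"];
  P.n_te = pars["n_te"]; P.n_tr = pars["n_tr"]; P.n_ti = pars["n_ti"];
  P.n_it = pars["n_it"];
  P.n_re = pars["n_re"]; P.n_rt = pars["n_rt"];

  const int n = 7, nc = Ac.nrow();
  const int dlag = (int)std::lround(P.delay / dt);
  const int H = dlag + 2;
  std::vector<double> hist((size_t)H * n);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < n; ++i) hist[(size_t)j * n + i] = x0[i];

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xc(nc, 0.0), xcn(nc);
  std::vector<double> ubuf(std::max(delay_steps, 1), 0.0);
  int ub = 0;

  NumericMatrix out(T, 2);
  double k1[7], k2[7], k3[7], k4[7], xt[7], xda[7], xdb[7], xdm[7];

  for (int k = 0; k < T; ++k) {
    double y = 0.0;
    for (int i = 0; i < n; ++i) y += Cobs[i] * x[i];
    double u = Dc(0, 0) * y;
    for (int j = 0; j < nc; ++j) u += Cc(0, j) * xc[j];
    out(k, 0) = y; out(k, 1) = u;
    if (!std::isfinite(y))
      stop("closed loop diverged at t = %.3f s", k * dt);
    // controller state update
    for (int i = 0; i < nc; ++i) {
      double acc = Bc(i, 0) * y;
      for (int j = 0; j < nc; ++j) acc += Ac(i, j) * xc[j];
      xcn[i] = acc;
    }
    xc.swap(xcn);
    // delayed stimulation
    double u_d = u;
    if (delay_steps > 0) {
      u_d = ubuf[ub];
      ubuf[ub] = u;
      ub = (ub + 1) % delay_steps;
    }
    // plant RK4 step
    auto read_hist = [&](int step, double* o) {
      int idx = ((step % H) + H) % H;
      const double* src = &hist[(size_t)idx * n];
      for (int i = 0; i < n; ++i) o[i] = src[i];
    };
    if (dlag == 0) {
      for (int i = 0; i < n; ++i) { xda[i] = x[i]; xdb[i] = x[i]; xdm[i] = x[i]; }
    } else {
      read_hist(k - dlag, xda);
      read_hist(k - dlag + 1, xdb);
      for (int i = 0; i < n; ++i) xdm[i] = 0.5 * (xda[i] + xdb[i]);
    }
    double exo[7];
    for (int i = 0; i < n; ++i) exo[i] = Bvec[i] * u_d + Noise(k, i);
    ct_deriv(P, x.data(), xda, exo, k1);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    ct_deriv(P, xt, xdm, exo, k2);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    ct_deriv(P, xt, xdm, exo, k3);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * k3[i];
    ct_deriv(P, xt, xdb, exo, k4);
    for (int i = 0; i < n; ++i) {
      x[i] += dt * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]) / 6.0;
      if (!std::isfinite(x[i]))
        stop("closed loop diverged at t = %.3f s", k * dt);
    }
    int idx = ((k + 1) % H + H) % H;
    for (int i = 0; i < n; ++i) hist[(size_t)idx * n + i] = x[i];
  }
  return out;
}
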