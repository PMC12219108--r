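// Sequential kernels: fixed-step RK4 oscillator integration, reservoir
// drive/forecast loops. Everything here is deterministic; all random draws
// happen on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double wrap_pi(double x) {
  // wrap to [-pi, pi)
  const double two_pi = 2.0 * M_PI;
  double y = x + M_PI;
  y -= two_pi * std::floor(y / two_pi);
  double r = y - M_PI;
  // guard the rounding edge so the result stays in [-pi, pi)
  if (r >= M_PI) r -= two_pi;
  if (r < -M_PI) r += two_pi;
  return r;
}

// dtheta_i/dt = omega_i + (K/N) sum_j sin(theta_j - theta_i) ; the j = i
// self-term is retained as written (it is zero for the standard model).
static vec kuramoto_deriv(const vec& th, const vec& omega, double K) {
  const uword N = th.n_elem;
  vec d(N);
  for (uword i = 0; i < N; ++i) {
    double s = 0.0;
    for (uword j = 0; j < N; ++j) s += std::sin(th(j) - th(i));
    d(i) = omega(i) + K / double(N) * s;
  }
  return d;
}

// bi-harmonic coupling; the j = i self-term contributes sin(g1) + a sin(g2).
static vec biharmonic_deriv(const vec& th, const vec& omega, double K,
                            double g1, double g2, double a) {
  const uword N = th.n_elem;
  vec d(N);
  for (uword i = 0; i < N; ++i) {
    double s = 0.0;
    for (uword j = 0; j < N; ++j) {
      double dphi = th(j) - th(i);
      s += std::sin(dphi + g1) + a * std::sin(2.0 * dphi + g2);
    }
    d(i) = omega(i) + K / double(N) * s;
  }
  return d;
}

// [[Rcpp::export]]
arma::mat rk4_integrate_phases(const arma::vec& init, const arma::vec& omega,
                               double coupling, double dt, int n_steps,
                               bool biharmonic, double gamma1, double gamma2,
                               double second_harmonic_scale) {
  const uword N = init.n_elem;
  mat out(n_steps + 1, N);
  vec th = init;
  for (uword i = 0; i < N; ++i) th(i) = wrap_pi(th(i));
  out.row(0) = th.t();
  for (int s = 1; s <= n_steps; ++s) {
    vec k1, k2, k3, k4;
    if (biharmonic) {
      k1 = biharmonic_deriv(th, omega, coupling, gamma1, gamma2, second_harmonic_scale);
      k2 = biharmonic_deriv(th + 0.5 * dt * k1, omega, coupling, gamma1, gamma2, second_harmonic_scale);
      k3 = biharmonic_deriv(th + 0.5 * dt * k2, omega, coupling, gamma1, gamma2, second_harmonic_scale);
      k4 = biharmonic_deriv(th + dt * k3, omega, coupling, gamma1, gamma2, second_harmonic_scale);
    } else {
      k1 = kuramoto_deriv(th, omega, coupling);
      k2 = kuramoto_deriv(th + 0.5 * dt * k1, omega, coupling);
      k3 = kuramoto_deriv(th + 0.5 * dt * k2, omega, coupling);
      k4 = kuramoto_deriv(th + dt * k3, omega, coupling);
    }
    th += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!th.is_finite())
      Rcpp::stop("integration produced a non-finite state at step %d", s);
    for (uword i = 0; i < N; ++i) th(i) = wrap_pi(th(i));
    out.row(s) = th.t();
  }
  return out;
}

// Phase-component form of the Kuramoto model: interleaved state
// (x1, y1, x2, y2, ...). The coupling sum collapses to x_i*Sy - y_i*Sx.
static vec component_deriv(const vec& u, const vec& omega, double K) {
  const uword N = omega.n_elem;
  double Sx = 0.0, Sy = 0.0;
  for (uword i = 0; i < N; ++i) { Sx += u(2 * i); Sy += u(2 * i + 1); }
  vec d(2 * N);
  for (uword i = 0; i < N; ++i) {
    double x = u(2 * i), y = u(2 * i + 1);
    double s = x * Sy - y * Sx;  // sum_j (y_j x_i - x_j y_i)
    d(2 * i) = -omega(i) * y - K * y / double(N) * s;
    d(2 * i + 1) = omega(i) * x + K * x / double(N) * s;
  }
  return d;
}

// [[Rcpp::export]]
arma::vec kuramoto_component_deriv_cpp(const arma::vec& u, const arma::vec& omega,
                                       double coupling) {
  return component_deriv(u, omega, coupling);
}

static vec expert_rk4(const vec& u, const vec& omega, double K, double dt) {
  vec k1 = component_deriv(u, omega, K);
  vec k2 = component_deriv(u + 0.5 * dt * k1, omega, K);
  vec k3 = component_deriv(u + 0.5 * dt * k2, omega, K);
  vec k4 = component_deriv(u + dt * k3, omega, K);
  return u + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// [[Rcpp::export]]
arma::vec expert_step_cpp(const arma::vec& u, const arma::vec& omega,
                          double coupling, double dt) {
  vec out = expert_rk4(u, omega, coupling, dt);
  if (!out.is_finite()) Rcpp::stop("expert one-step integration produced a non-finite state");
  return out;
}

// readout nonlinearity g: 1-based odd positions linear, even positions squared
static vec apply_g_vec(const vec& r) {
  vec g = r;
  for (uword i = 1; i < r.n_elem; i += 2) g(i) = r(i) * r(i);
  return g;
}

// per-oscillator magnitude normalization; returns false on a degenerate pair
static bool normalize_pairs(vec& u) {
  const uword N = u.n_elem / 2;
  for (uword i = 0; i < N; ++i) {
    double x = u(2 * i), y = u(2 * i + 1);
    if (!std::isfinite(x) || !std::isfinite(y)) return false;
    double m = std::hypot(x, y);
    if (m < 1e-12) return false;
    u(2 * i) = x / m;
    u(2 * i + 1) = y / m;
  }
  return true;
}

// [[Rcpp::export]]
arma::mat drive_cpp(const arma::sp_mat& A, const arma::mat& B,
                    const arma::vec& r0, const arma::mat& inputs) {
  const uword n = inputs.n_rows;
  mat states(A.n_rows, n);
  vec r = r0;
  for (uword t = 0; t < n; ++t) {
    r = tanh(A * r + B * inputs.row(t).t());
    if (!r.is_finite())
      Rcpp::stop("reservoir state became non-finite at step %d", (int)(t + 1));
    states.col(t) = r;
  }
  return states;
}

// [[Rcpp::export]]
Rcpp::List hybrid_drive_cpp(const arma::sp_mat& A, const arma::mat& B,
                            const arma::vec& r0, const arma::mat& inputs,
                            const arma::vec& omega, double coupling, double dt) {
  const uword n = inputs.n_rows;
  const uword Du = inputs.n_cols;
  mat states(A.n_rows, n), experts(Du, n);
  vec r = r0;
  for (uword t = 0; t < n; ++t) {
    vec u = inputs.row(t).t();
    vec ut = expert_rk4(u, omega, coupling, dt);
    if (!ut.is_finite())
      Rcpp::stop("expert integration failed at step %d", (int)(t + 1));
    r = tanh(A * r + B * join_cols(ut, u));
    if (!r.is_finite())
      Rcpp::stop("reservoir state became non-finite at step %d", (int)(t + 1));
    states.col(t) = r;
    experts.col(t) = ut;
  }
  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("experts") = experts);
}

// Closed-loop forecast. hybrid = false: r <- tanh(A r + B u); u <- norm(C g(r)).
// hybrid = true: utilde <- expert(u); r <- tanh(A r + B [utilde; u]);
//                u <- norm(C [utilde; g(r)]).
// On a degenerate normalization the forecast is truncated and the 1-based
// failing step index is reported (0 = no failure).
// [[Rcpp::export]]
Rcpp::List forecast_cpp(const arma::sp_mat& A, const arma::mat& B,
                        const arma::mat& C, const arma::vec& r0,
                        const arma::vec& u0, int n_steps, bool hybrid,
                        const arma::vec& omega, double coupling, double dt) {
  vec r = r0, u = u0;
  const uword Du = u0.n_elem;
  mat out(n_steps, Du);
  int failure = 0;
  int recorded = 0;
  for (int t = 0; t < n_steps; ++t) {
    vec y;
    if (hybrid) {
      vec ut = expert_rk4(u, omega, coupling, dt);
      if (!ut.is_finite()) { failure = t + 1; break; }
      r = tanh(A * r + B * join_cols(ut, u));
      y = C * join_cols(ut, apply_g_vec(r));
    } else {
      r = tanh(A * r + B * u);
      y = C * apply_g_vec(r);
    }
    if (!normalize_pairs(y)) { failure = t + 1; break; }
    out.row(t) = y.t();
    u = y;
    ++recorded;
  }
  mat rec = (recorded > 0) ? mat(out.rows(0, recorded - 1)) : mat(0, Du);
  return Rcpp::List::create(
      Rcpp::Named("states") = rec,
      Rcpp::Named("n_recorded") = recorded,
      Rcpp::Named("failure_step") = failure,
      Rcpp::Named("final_reservoir_state") = r);
}

// Pure expert control: iterate the one-step integrator with the same
// per-step magnitude normalization the reservoirs use.
// [[Rcpp::export]]
Rcpp::List expert_forecast_cpp(const arma::vec& u0, int n_steps,
                               const arma::vec& omega, double coupling,
                               double dt) {
  vec u = u0;
  mat out(n_steps, u0.n_elem);
  int failure = 0, recorded = 0;
  for (int t = 0; t < n_steps; ++t) {
    vec y = expert_rk4(u, omega, coupling, dt);
    if (!normalize_pairs(y)) { failure = t + 1; break; }
    out.row(t) = y.t();
    u = y;
    ++recorded;
  }
  mat rec = (recorded > 0) ? mat(out.rows(0, recorded - 1)) : mat(0, u0.n_elem);
  return Rcpp::List::create(
      Rcpp::Named("states") = rec,
      Rcpp::Named("n_recorded") = recorded,
      Rcpp::Named("failure_step") = failure);
}
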