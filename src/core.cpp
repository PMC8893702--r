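// Core numerics: Euler simulation of the E/I firing-rate network,
// backpropagation-through-time gradients for the masked squared error,
// and the breakpoint time-warp distance profile used by the unit-level
// timing indices. Kept in C++ because training updates run once per trial
// over hundreds of Euler steps and the warp scan is O(T^2) per unit.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double softplus_capped(double x, double cap) {
  double r = (x > 30.0) ? x : std::log1p(std::exp(x));
  return (r > cap) ? cap : r;
}

// derivative of min(softplus(x), cap): sigmoid below the cap, 0 above
static inline double softplus_grad(double x, double cap) {
  double r = (x > 30.0) ? x : std::log1p(std::exp(x));
  if (r >= cap) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Forward simulation.
//   Weff   : N x N effective recurrent weights (already clipped and signed)
//   Win    : N x 2 input weights
//   wout   : length-N output weights
//   inputs : T x 2 external input time series
//   alpha  : dt / tau
//   noise_sd : per-step additive noise s.d. (already includes the
//              sqrt(2*alpha)*sigma or alternative scaling)
// Returns rates (N x T) and output (length T). x_0 = 0.
// [[Rcpp::export]]
List cpp_simulate(const arma::mat& Weff, const arma::mat& Win,
                  const arma::vec& wout, const arma::mat& inputs,
                  double alpha, double noise_sd, double rate_bound) {
  const int N = Weff.n_rows;
  const int T = inputs.n_rows;
  arma::mat R(N, T);
  arma::vec o(T);
  arma::vec x(N, arma::fill::zeros);
  arma::vec r(N);
  r.fill(softplus_capped(0.0, rate_bound));  // r at x = 0

  for (int t = 0; t < T; ++t) {
    arma::vec drive = Weff * r + Win * inputs.row(t).t();
    x = (1.0 - alpha) * x + alpha * drive;
    if (noise_sd > 0.0) {
      for (int i = 0; i < N; ++i) x[i] += noise_sd * ::norm_rand();
    }
    if (!x.is_finite())
      stop("non-finite state at step %d of the simulation", t + 1);
    for (int i = 0; i < N; ++i) r[i] = softplus_capped(x[i], rate_bound);
    R.col(t) = r;
    o[t] = arma::dot(wout, r);
  }
  return List::create(_["rates"] = R, _["output"] = o);
}

// Forward simulation returning only the output trace (no rate storage);
// used by trial scoring loops where the rates are not needed.
// [[Rcpp::export]]
arma::vec cpp_simulate_output(const arma::mat& Weff, const arma::mat& Win,
                              const arma::vec& wout,
                              const arma::mat& inputs, double alpha,
                              double noise_sd, double rate_bound) {
  const int N = Weff.n_rows;
  const int T = inputs.n_rows;
  arma::vec o(T);
  arma::vec x(N, arma::fill::zeros);
  arma::vec r(N);
  r.fill(softplus_capped(0.0, rate_bound));
  for (int t = 0; t < T; ++t) {
    arma::vec drive = Weff * r + Win * inputs.row(t).t();
    x = (1.0 - alpha) * x + alpha * drive;
    if (noise_sd > 0.0) {
      for (int i = 0; i < N; ++i) x[i] += noise_sd * ::norm_rand();
    }
    if (!x.is_finite())
      stop("non-finite state at step %d of the simulation", t + 1);
    for (int i = 0; i < N; ++i) r[i] = softplus_capped(x[i], rate_bound);
    o[t] = arma::dot(wout, r);
  }
  return o;
}

// One trial of forward + BPTT for the masked sum-of-squares error.
// Wrec holds the raw (trainable) recurrent weights; the forward pass uses
// effective weights relu(Wrec) * sign[j] per presynaptic column, with a
// zero diagonal. Gradients pass through the rectifier with subgradient 0
// below zero. Win is frozen, so its gradient is not computed.
// [[Rcpp::export]]
List cpp_bptt(const arma::mat& Wrec, const arma::vec& sgn,
              const arma::mat& Win, const arma::vec& wout,
              const arma::mat& inputs, const arma::vec& target,
              const arma::vec& mask, double alpha, double noise_sd,
              double rate_bound) {
  const int N = Wrec.n_rows;
  const int T = inputs.n_rows;

  arma::mat Weff = Wrec;
  Weff.transform([](double w) { return w > 0.0 ? w : 0.0; });
  Weff.diag().zeros();
  Weff.each_row() %= sgn.t();  // column j carries sign of unit j

  arma::mat X(N, T), R(N, T + 1);
  arma::vec o(T);
  {
    arma::vec x(N, arma::fill::zeros);
    arma::vec r(N);
    r.fill(softplus_capped(0.0, rate_bound));
    R.col(0) = r;
    for (int t = 0; t < T; ++t) {
      arma::vec drive = Weff * r + Win * inputs.row(t).t();
      x = (1.0 - alpha) * x + alpha * drive;
      if (noise_sd > 0.0) {
        for (int i = 0; i < N; ++i) x[i] += noise_sd * ::norm_rand();
      }
      if (!x.is_finite())
        stop("non-finite state at step %d of the forward pass", t + 1);
      for (int i = 0; i < N; ++i) r[i] = softplus_capped(x[i], rate_bound);
      X.col(t) = x;
      R.col(t + 1) = r;
      o[t] = arma::dot(wout, r);
    }
  }

  arma::vec err = o - target;
  double loss = arma::dot(mask, arma::square(err));

  arma::mat WeffT = Weff.t();
  arma::mat P(N, T);  // adjoint dE/dx_t per step, for one batched GEMM
  arma::vec gWout(N, arma::fill::zeros);
  arma::vec p(N, arma::fill::zeros);  // dE/dx_{t+1}
  for (int t = T - 1; t >= 0; --t) {
    double e = 2.0 * mask[t] * err[t];
    gWout += e * R.col(t + 1);
    arma::vec dr = wout * e + alpha * (WeffT * p);
    arma::vec fp(N);
    for (int i = 0; i < N; ++i) fp[i] = softplus_grad(X(i, t), rate_bound);
    p = (1.0 - alpha) * p + fp % dr;
    P.col(t) = p;
  }
  // gWeff = alpha * sum_t p_t r_{t-1}^T
  arma::mat gWeff = alpha * (P * R.cols(0, T - 1).t());

  // chain rule through relu(Wrec) * sign
  arma::mat gWrec = gWeff;
  gWrec.each_row() %= sgn.t();
  gWrec.elem(arma::find(Wrec <= 0.0)).zeros();
  gWrec.diag().zeros();

  return List::create(_["loss"] = loss, _["output"] = o,
                      _["gWrec"] = gWrec, _["gWout"] = gWout);
}

// Warp the long-interval trace y onto the short grid for breakpoint tau:
// identity up to tau, then indices tau + alpha*(t - tau) with
// alpha = (Tl - tau) / (Ts - tau), linearly interpolated. tau = Ts gives
// the pure-absolute identity warp (first Ts samples of y). 1-based tau in
// [0, Ts]; returns a length-Ts trace.
static arma::vec warp_long(const arma::vec& y, int tau, int Ts) {
  const int Tl = y.n_elem;
  arma::vec out(Ts);
  for (int t = 1; t <= tau; ++t) out[t - 1] = y[t - 1];
  if (tau < Ts) {
    double a = (double)(Tl - tau) / (double)(Ts - tau);
    for (int t = tau + 1; t <= Ts; ++t) {
      double pos = tau + a * (t - tau);  // 1-based fractional index
      if (pos >= Tl) { out[t - 1] = y[Tl - 1]; continue; }
      int lo = (int)std::floor(pos);
      if (lo < 1) lo = 1;
      double frac = pos - lo;
      out[t - 1] = (1.0 - frac) * y[lo - 1] + frac * y[lo];
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_warp_long(const arma::vec& y, int tau, int Ts) {
  return warp_long(y, tau, Ts);
}

// Squared-distance profile Dist(tau) between a short trace x and the
// warped long trace, evaluated at the requested breakpoints.
// [[Rcpp::export]]
arma::vec cpp_dist_profile(const arma::vec& x, const arma::vec& y,
                           const arma::ivec& taus) {
  const int Ts = x.n_elem;
  arma::vec out(taus.n_elem);
  for (arma::uword k = 0; k < taus.n_elem; ++k) {
    arma::vec w = warp_long(y, taus[k], Ts);
    out[k] = arma::accu(arma::square(x - w));
  }
  return out;
}
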