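#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Population firing-rate transfer H(x) = (a x - b) / (1 - exp(-d (a x - b))),
// with the removable singularity at a x = b filled by its limit 1/d.
static inline double firing_rate_scalar(double x, double a, double b, double d) {
  double u = a * x - b;
  if (u == 0.0) return 1.0 / d;
  double denom = -expm1(-d * u);
  if (denom == 0.0) return 1.0 / d; // |u| below double resolution of expm1
  return u / denom;
}

// Euler-Maruyama integration of the relaxed mean-field gating equations
//   dS_i = [-S_i/tau_s + r (1 - S_i) H(x_i)] dt + sigma sqrt(dt) dW_i
//   x_i  = w_i J S_i + G J sum_j C_ij S_j + I_i
// Noise is drawn from R's RNG (N draws per step, in region order) so a pure-R
// loop with the same seed reproduces the trajectory bit-for-bit.
// Returns rows n_burn+1 .. n_steps of the S trajectory.
// [[Rcpp::export]]
List cpp_simulate_neural(const arma::mat& C, const arma::vec& w,
                         const arma::vec& I, double G, double sigma,
                         double r, double tau_s, double a, double b, double d,
                         double J, double dt, int n_steps, int n_burn,
                         double S0) {
  const int N = C.n_rows;
  arma::vec S(N, arma::fill::value(S0));
  arma::vec x(N), drift(N);
  const int n_rec = n_steps - n_burn;
  arma::mat S_series(n_rec, N);
  const double sq = sigma * std::sqrt(dt);
  long clamp_count = 0;

  for (int t = 0; t < n_steps; ++t) {
    x = w % (J * S) + (G * J) * (C * S) + I;
    for (int i = 0; i < N; ++i)
      drift(i) = -S(i) / tau_s + r * (1.0 - S(i)) * firing_rate_scalar(x(i), a, b, d);
    S += dt * drift;
    if (sigma > 0.0) {
      NumericVector eps = rnorm(N);
      for (int i = 0; i < N; ++i) S(i) += sq * eps[i];
    }
    for (int i = 0; i < N; ++i) {
      if (S(i) < 0.0) { S(i) = 0.0; ++clamp_count; }
      else if (S(i) > 1.0) { S(i) = 1.0; ++clamp_count; }
    }
    if (t >= n_burn) S_series.row(t - n_burn) = S.t();
  }
  return List::create(_["S_series"] = S_series,
                      _["clamp_count"] = (double)clamp_count);
}

// Balloon-Windkessel hemodynamics driven by a gating trajectory (one row per
// neural step), integrated by explicit Euler from the resting state
// (z, f, v, q) = (0, 1, 1, 1) at step `dt / substeps`, with BOLD recorded
// every `subsample` neural steps.
// [[Rcpp::export]]
arma::mat cpp_simulate_bold(const arma::mat& S_series, double dt,
                            double kappa, double gamma, double tau,
                            double alpha, double rho, double V0,
                            double k1, double k2, double k3,
                            int subsample, int substeps) {
  const int T = S_series.n_rows, N = S_series.n_cols;
  arma::vec z(N, arma::fill::zeros);
  arma::vec f(N, arma::fill::ones), v(N, arma::fill::ones), q(N, arma::fill::ones);
  const int n_out = T / subsample;
  arma::mat Y(n_out, N);
  const double inv_alpha = 1.0 / alpha;
  const double log1mrho = std::log(1.0 - rho);
  const double h = dt / substeps;
  int row = 0;

  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < substeps; ++s) {
      for (int i = 0; i < N; ++i) {
        double vexp = std::pow(v(i), inv_alpha);           // v^(1/alpha)
        double E = -std::expm1(log1mrho / f(i));           // 1 - (1-rho)^(1/f)
        double dz = S_series(t, i) - kappa * z(i) - gamma * (f(i) - 1.0);
        double df = z(i);
        double dv = (f(i) - vexp) / tau;
        double dq = (f(i) / rho * E - q(i) * vexp / v(i)) / tau;
        z(i) += h * dz;
        f(i) += h * df;
        v(i) += h * dv;
        q(i) += h * dq;
      }
    }
    if ((t + 1) % subsample == 0) {
      for (int i = 0; i < N; ++i)
        Y(row, i) = V0 * (k1 * (1.0 - q(i)) + k2 * (1.0 - q(i) / v(i)) + k3 * (1.0 - v(i)));
      ++row;
    }
  }
  return Y;
}
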