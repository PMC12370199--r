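#include <Rcpp.h>
using namespace Rcpp;

// State layout (15): rA rAB rB | aA aAB aB | eA eAB eB | dA dAB dB | xA xAB xB
// Input layout (6):  iA iAB iB | tA tAB tB

struct Pars {
  double beta_e, beta_i, g, kappa;
  double tau_r, tau_a, tau_e, tau_d;
  double k_F, theta_F, gamma, tau_X;
};

static Pars unpack(const List& p) {
  Pars q;
  q.beta_e = as<double>(p["beta_e"]);
  q.beta_i = as<double>(p["beta_i"]);
  q.g = as<double>(p["g"]);
  q.kappa = as<double>(p["kappa"]);
  q.tau_r = as<double>(p["tau_r"]);
  q.tau_a = as<double>(p["tau_a"]);
  q.tau_e = as<double>(p["tau_e"]);
  q.tau_d = as<double>(p["tau_d"]);
  q.k_F = as<double>(p["k_F"]);
  q.theta_F = as<double>(p["theta_F"]);
  q.gamma = as<double>(p["gamma"]);
  q.tau_X = as<double>(p["tau_X"]);
  return q;
}

static inline double sigmoidF(double u, const Pars& p) {
  return 1.0 / (1.0 + std::exp(p.k_F * (-u + p.theta_F)));
}

// Deterministic right-hand side; noise values enter only through the state's
// chi components inside the sigmoid argument. chi drift is mean reversion.
static void drift_raw(const double* s, const double* in, const Pars& p,
                      double* ds) {
  const double rA = s[0], rAB = s[1], rB = s[2];
  const double uA = p.beta_e * s[9] * s[6] - p.beta_i * rB -
                    2.0 * p.beta_i * rAB - p.g * s[3] + in[0] + in[3] + s[12];
  const double uAB = p.beta_e * s[10] * s[7] - p.beta_i * (rA + rB) -
                     p.g * s[4] + in[1] + in[4] + s[13];
  const double uB = p.beta_e * s[11] * s[8] - p.beta_i * rA -
                    2.0 * p.beta_i * rAB - p.g * s[5] + in[2] + in[5] + s[14];
  ds[0] = (-rA + sigmoidF(uA, p)) / p.tau_r;
  ds[1] = (-rAB + sigmoidF(uAB, p)) / p.tau_r;
  ds[2] = (-rB + sigmoidF(uB, p)) / p.tau_r;
  for (int k = 0; k < 3; ++k) {
    ds[3 + k] = (-s[3 + k] + s[k]) / p.tau_a;
    ds[6 + k] = (-s[6 + k] + s[k]) / p.tau_e;
    ds[9 + k] = (-s[9 + k] + (1.0 - p.kappa * s[k])) / p.tau_d;
    ds[12 + k] = -s[12 + k] / p.tau_X;
  }
}

// [[Rcpp::export]]
NumericVector drift_cpp(NumericVector state, NumericVector input, List pars) {
  if (state.size() != 15) stop("state must have 15 elements");
  if (input.size() != 6) stop("input must have 6 elements");
  Pars p = unpack(pars);
  NumericVector ds(15);
  drift_raw(state.begin(), input.begin(), p, ds.begin());
  return ds;
}

static inline void em_step(double* s, const double* in, const Pars& p,
                           double dt, double noise_sd, bool exact_ou,
                           double ou_decay, double ou_sd) {
  double ds[15];
  drift_raw(s, in, p, ds);
  for (int j = 0; j < 12; ++j) s[j] += dt * ds[j];
  for (int k = 0; k < 3; ++k) {
    double& x = s[12 + k];
    if (exact_ou) {
      x = ou_decay * x + ou_sd * norm_rand();
    } else {
      x += dt * ds[12 + k] + noise_sd * norm_rand();
    }
  }
}

// Integrate one trial, recording the full state history. Row i holds the
// state at time (i-1)*dt; row 1 is the initial condition. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix integrate_cpp(NumericMatrix inputs, List pars, double dt,
                            NumericVector init, bool exact_ou) {
  if (inputs.ncol() != 6) stop("inputs must have 6 columns");
  if (init.size() != 15) stop("init must have 15 elements");
  Pars p = unpack(pars);
  const int n = inputs.nrow();
  NumericMatrix out(n, 15);
  double s[15];
  for (int j = 0; j < 15; ++j) { s[j] = init[j]; out(0, j) = s[j]; }
  const double noise_sd = p.gamma * std::sqrt(2.0 * dt / p.tau_X);
  const double ou_decay = std::exp(-dt / p.tau_X);
  const double ou_sd = p.gamma * std::sqrt(1.0 - ou_decay * ou_decay);
  double in[6];
  for (int i = 1; i < n; ++i) {
    for (int c = 0; c < 6; ++c) in[c] = inputs(i - 1, c);
    em_step(s, in, p, dt, noise_sd, exact_ou, ou_decay, ou_sd);
    for (int j = 0; j < 15; ++j) {
      if (!std::isfinite(s[j]))
        stop("non-finite state at step %d, variable %d", i, j + 1);
      out(i, j) = s[j];
    }
  }
  return out;
}

// As sim_trials_cpp below, but with the noise path frozen by the caller:
// chi0 holds the initial noise values (3 per trial) and z the standard-
// normal increments (3 per step per trial, trial-major). Used by the
// fitting objective so every candidate sees the identical noise
// realization (common random numbers).
// [[Rcpp::export]]
NumericMatrix sim_trials_frozen_cpp(NumericMatrix inputs, List pars,
                                    double dt, int win_lo, int win_hi,
                                    NumericVector init12,
                                    NumericVector chi0, NumericVector z) {
  if (inputs.ncol() != 6) stop("inputs must have 6 columns");
  if (init12.size() != 12) stop("init12 must have 12 elements");
  Pars p = unpack(pars);
  const int n = inputs.nrow();
  if (win_lo < 0 || win_hi > n || win_lo >= win_hi)
    stop("report window outside the simulated trial");
  const int n_trials = chi0.size() / 3;
  if ((int)z.size() != n_trials * 3 * (n - 1))
    stop("frozen noise has the wrong length");
  NumericMatrix out(n_trials, 6);
  const double noise_sd = p.gamma * std::sqrt(2.0 * dt / p.tau_X);
  const double win_n = static_cast<double>(win_hi - win_lo);
  double s[15], in[6], ds[15];
  for (int tr = 0; tr < n_trials; ++tr) {
    for (int j = 0; j < 12; ++j) s[j] = init12[j];
    for (int k = 0; k < 3; ++k) s[12 + k] = chi0[3 * tr + k];
    const double* ztr = z.begin() + (R_xlen_t)tr * 3 * (n - 1);
    double acc[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (i >= win_lo && i < win_hi) {
        for (int k = 0; k < 3; ++k) {
          acc[k] += s[k];
          acc[3 + k] += s[6 + k];
        }
      }
      if (i + 1 < n) {
        for (int c = 0; c < 6; ++c) in[c] = inputs(i, c);
        drift_raw(s, in, p, ds);
        for (int j = 0; j < 12; ++j) s[j] += dt * ds[j];
        const double* zi = ztr + (R_xlen_t)i * 3;
        for (int k = 0; k < 3; ++k)
          s[12 + k] += dt * ds[12 + k] + noise_sd * zi[k];
      }
    }
    for (int c = 0; c < 6; ++c) out(tr, c) = acc[c] / win_n;
  }
  return out;
}

// Run n_trials independent trials of the same stimulus and return the
// time-averaged firing rates (r) and recurrent excitation (e) of the three
// units over the grid-index window [win_lo, win_hi) (0-based). Each trial
// restarts from init12 (r, a, e, d); chi is drawn fresh from the stationary
// distribution N(0, gamma^2). Columns: rA rAB rB eA eAB eB.
// [[Rcpp::export]]
NumericMatrix sim_trials_cpp(NumericMatrix inputs, List pars, double dt,
                             int n_trials, int win_lo, int win_hi,
                             NumericVector init12, bool exact_ou) {
  if (inputs.ncol() != 6) stop("inputs must have 6 columns");
  if (init12.size() != 12) stop("init12 must have 12 elements");
  Pars p = unpack(pars);
  const int n = inputs.nrow();
  if (win_lo < 0 || win_hi > n || win_lo >= win_hi)
    stop("report window outside the simulated trial");
  NumericMatrix out(n_trials, 6);
  const double noise_sd = p.gamma * std::sqrt(2.0 * dt / p.tau_X);
  const double ou_decay = std::exp(-dt / p.tau_X);
  const double ou_sd = p.gamma * std::sqrt(1.0 - ou_decay * ou_decay);
  const double win_n = static_cast<double>(win_hi - win_lo);
  double s[15], in[6];
  for (int tr = 0; tr < n_trials; ++tr) {
    for (int j = 0; j < 12; ++j) s[j] = init12[j];
    for (int j = 12; j < 15; ++j) s[j] = p.gamma * norm_rand();
    double acc[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (i >= win_lo && i < win_hi) {
        for (int k = 0; k < 3; ++k) {
          acc[k] += s[k];
          acc[3 + k] += s[6 + k];
        }
      }
      if (i + 1 < n) {
        for (int c = 0; c < 6; ++c) in[c] = inputs(i, c);
        em_step(s, in, p, dt, noise_sd, exact_ou, ou_decay, ou_sd);
      }
    }
    for (int c = 0; c < 6; ++c) out(tr, c) = acc[c] / win_n;
  }
  return out;
}
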