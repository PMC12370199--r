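STATE_VARS <- c("r_A", "r_AB", "r_B", "a_A", "a_AB", "a_B",
                "e_A", "e_AB", "e_B", "d_A", "d_AB", "d_B",
                "chi_A", "chi_AB", "chi_B")

#' Sigmoidal firing-rate function
#'
#' `F(u) = 1 / (1 + exp(k_F * (-u + theta_F)))`: the shared output
#' nonlinearity of the three competition units. Strictly increasing, bounded
#' in (0, 1), with `F(theta_F) = 0.5`.
#'
#' @param u net input (vectorized).
#' @param params a [model_params()] object (uses `k_F`, `theta_F`).
#' @return Firing rate(s) in (0, 1).
#' @export
#' @examples
#' firing_rate(0.2)  # at threshold: 0.5
firing_rate <- function(u, params = model_params()) {
  1 / (1 + exp(params$k_F * (-u + params$theta_F)))
}

#' Deterministic drift of the competition model
#'
#' Right-hand side of the 15-variable system at one instant. For each unit
#' `k` in `{A, AB, B}` the firing rate obeys
#' `tau_r * r_k' = -r_k + F(beta_e d_k e_k - inhibition_k - g a_k + i_k +
#' t_k + chi_k)`, where the peripheral units A and B are inhibited by
#' `beta_i * r_other + 2 beta_i * r_AB` (inhibition from the central AB unit
#' is twice as strong) and the AB unit by `beta_i * (r_A + r_B)`. The slow
#' variables relax linearly: `tau_a a_k' = -a_k + r_k` (adaptation),
#' `tau_e e_k' = -e_k + r_k` (recurrent NMDA excitation),
#' `tau_d d_k' = -d_k + (1 - kappa r_k)` (synaptic depression). The noise
#' components contribute their mean reversion `-chi_k / tau_X`; their
#' stochastic part lives in [ou_step()].
#'
#' @param state numeric vector of the 15 state variables, in the order
#'   `r_A, r_AB, r_B, a_A, a_AB, a_B, e_A, e_AB, e_B, d_A, d_AB, d_B,
#'   chi_A, chi_AB, chi_B` (names optional).
#' @param input numeric vector of the six channel values
#'   `i_A, i_AB, i_B, t_A, t_AB, t_B` at the current instant.
#' @param params a [model_params()] object.
#' @return Named numeric vector of the 15 time derivatives (per ms).
#' @export
drift <- function(state, input, params = model_params()) {
  ds <- drift_cpp(as.numeric(state), as.numeric(input), params)
  setNames(ds, STATE_VARS)
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck input noise
#'
#' Advances `chi` by `dt` under `chi' = -chi / tau_X + gamma *
#' sqrt(2 / tau_X) * white noise`: the stationary distribution is
#' `N(0, gamma^2)` and the autocorrelation time is `tau_X`. With
#' `exact = TRUE` the exact Gaussian transition (decay `exp(-dt/tau_X)`) is
#' used instead of the Euler-Maruyama increment, for step-refinement checks.
#'
#' @param chi current noise value(s); each element advances independently.
#' @param params a [model_params()] object (uses `gamma`, `tau_X`, `dt`).
#' @param exact use the exact transition density instead of Euler-Maruyama.
#' @return Updated noise value(s).
#' @export
ou_step <- function(chi, params = model_params(), exact = FALSE) {
  dt <- params$dt
  if (dt <= 0) stop("`dt` must be positive")
  z <- rnorm(length(chi))
  if (exact) {
    decay <- exp(-dt / params$tau_X)
    decay * chi + params$gamma * sqrt(1 - decay^2) * z
  } else {
    chi - chi / params$tau_X * dt +
      params$gamma * sqrt(2 / params$tau_X) * sqrt(dt) * z
  }
}

# Default initial state: quiescent (r = a = e = 0, d = 1) except for a weak
# integration bias r_AB(0) = 0.25. Short ABA- sequences are initially heard
# as integrated (the build-up effect), and with a fully quiescent start the
# first A tone hands the opening competition to the peripheral units; the
# bias is calibrated so the first-triplet percept is split evenly at the
# equidominance frequency difference (4 st, no tactile input). The noise
# components start at their stationary distribution N(0, gamma^2).
INTEGRATION_BIAS <- 0.25

default_init_rates <- function(integration_bias = INTEGRATION_BIAS) {
  c(0, integration_bias, 0, rep(0, 6), rep(1, 3))
}

default_init <- function(params, integration_bias = INTEGRATION_BIAS) {
  c(default_init_rates(integration_bias), rnorm(3, 0, params$gamma))
}

#' Simulate one trial of the competition model
#'
#' Builds the driving inputs for `spec`, then integrates all 15 state
#' variables by fixed-step Euler-Maruyama (step `params$dt`). The default
#' initial condition is quiescent (`a = e = r = 0`, `d = 1`) apart from a
#' weak integration bias `r_AB(0) = 0.25` — short ABA- sequences are
#' initially heard as integrated (build-up), and the bias is calibrated so
#' the opening competition is even at the equidominance frequency
#' difference (4 st, no tactile input). Noise components start at their
#' stationary distribution `N(0, gamma^2)`. Override any of this via
#' `init`. The trace is reproducible bit-for-bit given `seed`.
#'
#' @param spec a [stimulus_spec()]; its `dt` is overridden by `params$dt`.
#' @param params a [model_params()] object.
#' @param input_params an [input_params()] object.
#' @param seed integer seed for the trial's noise.
#' @param init optional 15-vector of initial state (order as in [drift()]);
#'   `NA` entries fall back to the default.
#' @param exact_ou use the exact Ornstein-Uhlenbeck transition for the noise
#'   components (step-refinement studies); default Euler-Maruyama.
#' @return An object of class `"sim_trace"`: list with `time` (ms), `state`
#'   (matrix, one column per state variable), `inputs` (the
#'   `"input_series"` used), `seed`, and `params`.
#' @seealso [classify_percept()], [estimate_condition()]
#' @export
#' @examples
#' tr <- simulate_trial(stimulus_spec(5), seed = 1)
#' classify_percept(tr)
simulate_trial <- function(spec, params = model_params(),
                           input_params = tactstream::input_params(),
                           seed = NULL, init = NULL, exact_ou = FALSE) {
  spec$dt <- params$dt
  inputs <- build_inputs(spec, input_params)
  if (!is.null(seed)) set.seed(seed)
  init_full <- default_init(params)
  if (!is.null(init)) {
    if (length(init) != 15) stop("`init` must have 15 elements")
    keep <- !is.na(init)
    init_full[keep] <- init[keep]
  }
  state <- integrate_cpp(inputs$channels, params, params$dt, init_full,
                         exact_ou)
  colnames(state) <- STATE_VARS
  structure(list(time = inputs$time, state = state, inputs = inputs,
                 spec = spec, params = params, seed = seed),
            class = "sim_trace")
}

#' Tidy export of a simulation trace
#'
#' @param x a `"sim_trace"` from [simulate_trial()].
#' @param row.names,optional,... conventions of the generic; unused.
#' @return A long data frame with columns `time_ms`, `variable`, `value`.
#' @export
as.data.frame.sim_trace <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(time_ms = rep(x$time, times = ncol(x$state)),
             variable = rep(colnames(x$state), each = length(x$time)),
             value = as.vector(x$state))
}

#' @exportS3Method base::print
print.sim_trace <- function(x, ...) {
  cat("<sim_trace> ", length(x$time), " steps of ", x$params$dt,
      " ms; delta_f = ", x$spec$delta_f, " st, tactile = ",
      x$spec$tactile_condition,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), "\n", sep = "")
  invisible(x)
}
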