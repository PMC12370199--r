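# Independent transcription of the competition model's right-hand side,
# written directly from the published system of equations in a different
# style from the package implementation (double-entry bookkeeping oracle).
oracle_drift <- function(state, input, p) {
  s <- as.list(setNames(state, c("rA", "rAB", "rB", "aA", "aAB", "aB",
                                 "eA", "eAB", "eB", "dA", "dAB", "dB",
                                 "xA", "xAB", "xB")))
  i <- as.list(setNames(input, c("iA", "iAB", "iB", "tA", "tAB", "tB")))
  Fs <- function(u) 1 / (1 + exp(p$k_F * (-u + p$theta_F)))
  out <- with(c(s, i, p), {
    c((-rA + Fs(beta_e * dA * eA - beta_i * rB - 2 * beta_i * rAB -
                  g * aA + iA + tA + xA)) / tau_r,
      (-rAB + Fs(beta_e * dAB * eAB - beta_i * (rA + rB) -
                   g * aAB + iAB + tAB + xAB)) / tau_r,
      (-rB + Fs(beta_e * dB * eB - beta_i * rA - 2 * beta_i * rAB -
                  g * aB + iB + tB + xB)) / tau_r,
      (-aA + rA) / tau_a, (-aAB + rAB) / tau_a, (-aB + rB) / tau_a,
      (-eA + rA) / tau_e, (-eAB + rAB) / tau_e, (-eB + rB) / tau_e,
      (-dA + (1 - kappa * rA)) / tau_d,
      (-dAB + (1 - kappa * rAB)) / tau_d,
      (-dB + (1 - kappa * rB)) / tau_d,
      -xA / tau_X, -xAB / tau_X, -xB / tau_X)
  })
  setNames(out, tactstream:::STATE_VARS)
}

# A constant-state fake trace for testing the percept classification rule
# in isolation from the integrator.
constant_trace <- function(r_A, r_AB, r_B, n_triplets = 5, pp = 125) {
  time <- seq(0, n_triplets * 4 * pp - 1)
  state <- matrix(0, length(time), 15,
                  dimnames = list(NULL, tactstream:::STATE_VARS))
  state[, "r_A"] <- r_A
  state[, "r_AB"] <- r_AB
  state[, "r_B"] <- r_B
  state[, c("e_A", "e_AB", "e_B")] <- state[, c("r_A", "r_AB", "r_B")]
  structure(list(time = time, state = state,
                 spec = stimulus_spec(4, n_triplets = n_triplets,
                                      presentation_period = pp),
                 seed = NULL),
            class = "sim_trace")
}
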