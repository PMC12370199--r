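#' Double alpha-function input pulse
#'
#' Onset-plateau response of a tonotopic location in primary auditory cortex
#' to a tone (or tactile pulse) with onset at `t = 0`:
#' `H(t) * [e^2/alpha_1^2 * t^2 * exp(-2 t / alpha_1) +
#'          Lambda_2 * e^2/alpha_2^2 * t^2 * exp(-2 t / alpha_2)]`,
#' where `H` is the Heaviside function. The first (onset) component peaks at
#' exactly 1 at `t = alpha_1`; the second (plateau) component peaks at
#' `Lambda_2` at `t = alpha_2` and decays slowly, so the pulse outlasts the
#' tone itself.
#'
#' @param t time since pulse onset, ms (vectorized).
#' @param params an [input_params()] object.
#' @return Drive amplitude(s), dimensionless, non-negative.
#' @export
#' @examples
#' alpha_input(15)            # onset-component peak: 1 + plateau tail
#' alpha_input(c(-5, 0, 50))  # zero before and at onset
alpha_input <- function(t, params = input_params()) {
  a1 <- params$alpha_1
  a2 <- params$alpha_2
  l2 <- params$Lambda_2
  out <- exp(2) / a1^2 * t^2 * exp(-2 * t / a1) +
    l2 * exp(2) / a2^2 * t^2 * exp(-2 * t / a2)
  out[t < 0] <- 0
  out
}

#' Exponential tonotopic spread profiles
#'
#' `auditory_weight()` gives the amplitude of a tone's drive at a tonotopic
#' location `delta_f` semitones away from the tone's own frequency:
#' `M_a * exp(-delta_f / sigma_a)`. `tactile_weight()` is the analogous
#' profile for tactile pulses, with parameters `(M_t1, sigma_t1)` when pulses
#' are synchronized with a single tone sequence (`mode = "single"`; tactile
#' conditions A and B) and `(M_t2, sigma_t2)` when synchronized with both
#' (`mode = "dual"`; condition AB).
#'
#' @param delta_f tonotopic distance, semitones (>= 0, vectorized).
#' @param mode `"single"` or `"dual"` tactile alignment.
#' @param params an [input_params()] object.
#' @return Weight(s), dimensionless.
#' @export
#' @examples
#' auditory_weight(0)               # full amplitude at the tone's location
#' auditory_weight(3.1)             # one decay constant away
#' tactile_weight(4, mode = "dual") # nearly flat profile
auditory_weight <- function(delta_f, params = input_params()) {
  if (any(delta_f < 0)) stop("`delta_f` must be non-negative")
  params$M_a * exp(-delta_f / params$sigma_a)
}

#' @rdname auditory_weight
#' @export
tactile_weight <- function(delta_f, mode = c("single", "dual"),
                           params = input_params()) {
  mode <- match.arg(mode)
  if (any(delta_f < 0)) stop("`delta_f` must be non-negative")
  if (mode == "single") {
    params$M_t1 * exp(-delta_f / params$sigma_t1)
  } else {
    params$M_t2 * exp(-delta_f / params$sigma_t2)
  }
}

#' Pulse onset times of an ABA- trial
#'
#' Within each triplet starting at `t0`, A tones onset at `t0` and
#' `t0 + 2 * PP`, the B tone at `t0 + PP`, and `[t0 + 3 PP, t0 + 4 PP)` is
#' silent (`PP` = presentation period). Tactile onsets copy the A onsets
#' (condition `"A"`), the B onsets (`"B"`), all tone onsets (`"AB"`), or are
#' empty (`"off"`); condition A therefore delivers twice as many tactile
#' pulses per triplet as condition B.
#'
#' @param spec a [stimulus_spec()].
#' @return A list with numeric vectors `A`, `B` (tone onsets, ms) and
#'   `tact_A`, `tact_B` (tactile onsets coinciding with A and B tones).
#' @export
#' @examples
#' onset_schedule(stimulus_spec(4, "B", n_triplets = 1))
onset_schedule <- function(spec) {
  pp <- spec$presentation_period
  t0 <- (seq_len(spec$n_triplets) - 1) * 4 * pp
  a_on <- sort(c(t0, t0 + 2 * pp))
  b_on <- t0 + pp
  tact <- switch(spec$tactile_condition,
    off = list(tact_A = numeric(0), tact_B = numeric(0)),
    A = list(tact_A = a_on, tact_B = numeric(0)),
    B = list(tact_A = numeric(0), tact_B = b_on),
    AB = list(tact_A = a_on, tact_B = b_on)
  )
  c(list(A = a_on, B = b_on), tact)
}

# Sum of alpha-function pulses over a set of onsets, on the grid `time`.
# Tails superpose additively; nothing is truncated at tone offset.
pulse_train <- function(time, onsets, params) {
  drive <- numeric(length(time))
  for (on in onsets) drive <- drive + alpha_input(time - on, params)
  drive
}

#' Build the six driving input channels of a trial
#'
#' Constructs the tonotopic drive to the three competition units (A, AB, B)
#' on a uniform time grid. Tone pulse trains `I_A`, `I_B` (sums of
#' [alpha_input()] pulses over the trial's onsets) are mixed across the
#' three tonotopic locations by the auditory spread profile:
#' `i_A = w(0) I_A + w(df) I_B`, `i_AB = w(df/2) (I_A + I_B)`,
#' `i_B = w(df) I_A + w(0) I_B`. Tactile pulse trains `T_A`, `T_B` are mixed
#' identically by the tactile profile ([tactile_weight()]), in `"single"`
#' mode for conditions A and B and `"dual"` mode for condition AB.
#'
#' The grid is closed-open: `t = 0, dt, ..., duration - dt`, with `t = 0`
#' the first A onset.
#'
#' @param spec a [stimulus_spec()].
#' @param params an [input_params()] object.
#' @return An object of class `"input_series"`: a list with `time` (ms) and
#'   `channels`, a matrix with columns `i_A`, `i_AB`, `i_B`, `t_A`, `t_AB`,
#'   `t_B`.
#' @seealso [as.data.frame.input_series()] for tidy export.
#' @export
#' @examples
#' inp <- build_inputs(stimulus_spec(4, "B"))
#' colnames(inp$channels)
build_inputs <- function(spec, params = input_params()) {
  trains <- pulse_trains(spec, params)
  ch <- mix_channels(trains, spec, params)
  structure(list(time = trains$time, channels = ch, spec = spec,
                 params = params),
            class = "input_series")
}

# Candidate-independent part of the construction: the raw pulse trains only
# depend on the alpha-function timing parameters, not on the spread
# profiles, so they can be cached across objective evaluations.
pulse_trains <- function(spec, params) {
  time <- seq(0, trial_duration(spec) - spec$dt, by = spec$dt)
  sched <- onset_schedule(spec)
  out <- list(time = time,
              I_A = pulse_train(time, sched$A, params),
              I_B = pulse_train(time, sched$B, params),
              T_A = NULL, T_B = NULL)
  if (spec$tactile_condition != "off") {
    out$T_A <- pulse_train(time, sched$tact_A, params)
    out$T_B <- pulse_train(time, sched$tact_B, params)
  }
  out
}

mix_channels <- function(trains, spec, params) {
  df <- spec$delta_f
  w0 <- auditory_weight(0, params)
  wf <- auditory_weight(df, params)
  wh <- auditory_weight(df / 2, params)
  ch <- cbind(i_A = w0 * trains$I_A + wf * trains$I_B,
              i_AB = wh * (trains$I_A + trains$I_B),
              i_B = wf * trains$I_A + w0 * trains$I_B,
              t_A = 0, t_AB = 0, t_B = 0)
  if (spec$tactile_condition != "off") {
    mode <- if (spec$tactile_condition == "AB") "dual" else "single"
    v0 <- tactile_weight(0, mode, params)
    vf <- tactile_weight(df, mode, params)
    vh <- tactile_weight(df / 2, mode, params)
    ch[, "t_A"] <- v0 * trains$T_A + vf * trains$T_B
    ch[, "t_AB"] <- vh * (trains$T_A + trains$T_B)
    ch[, "t_B"] <- vf * trains$T_A + v0 * trains$T_B
  }
  ch
}

#' Tidy export of an input series
#'
#' @param x an `"input_series"` from [build_inputs()].
#' @param row.names,optional,... passed on conventions of the generic;
#'   unused.
#' @return A long data frame with columns `time_ms`, `channel`, `value`.
#' @export
as.data.frame.input_series <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  ch <- x$channels
  data.frame(time_ms = rep(x$time, times = ncol(ch)),
             channel = rep(colnames(ch), each = length(x$time)),
             value = as.vector(ch))
}

#' @exportS3Method base::print
print.input_series <- function(x, ...) {
  cat("<input_series> ", length(x$time), " samples, dt = ", x$spec$dt,
      " ms, delta_f = ", x$spec$delta_f, " st, tactile = ",
      x$spec$tactile_condition, "\n", sep = "")
  invisible(x)
}
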