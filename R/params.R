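#' Competition-stage model parameters
#'
#' Parameters of the three-population firing-rate competition model: recurrent
#' excitation `beta_e` (gated by synaptic depression), mutual inhibition
#' `beta_i` (the central AB unit inhibits the peripheral A and B units twice
#' as strongly as they inhibit each other), spike-frequency adaptation
#' strength `g`, synaptic-depression strength `kappa`, the time constants of
#' the firing rate (`tau_r`), adaptation (`tau_a`), recurrent NMDA excitation
#' (`tau_e`) and depression (`tau_d`) variables, the sigmoid slope `k_F` and
#' threshold `theta_F`, the noise strength `gamma` and timescale `tau_X`, and
#' the Euler-Maruyama step `dt`.
#'
#' Defaults are the reference parameter set used throughout the package.
#'
#' @param beta_e recurrent-excitation strength (dimensionless).
#' @param beta_i inhibition strength (dimensionless).
#' @param g adaptation strength (dimensionless).
#' @param kappa synaptic-depression strength, in `[0, 1]`.
#' @param tau_r,tau_a,tau_e,tau_d time constants, ms.
#' @param k_F sigmoid slope (dimensionless).
#' @param theta_F sigmoid threshold (dimensionless).
#' @param gamma Ornstein-Uhlenbeck noise strength (stationary sd).
#' @param tau_X Ornstein-Uhlenbeck timescale, ms.
#' @param dt integration step, ms.
#' @return A named list of class `"model_params"`.
#' @seealso [input_params()], [stimulus_spec()], [simulate_trial()]
#' @export
#' @examples
#' model_params()
#' model_params(gamma = 0)  # noise-free dynamics
model_params <- function(beta_e = 0.85, beta_i = 0.3, g = 0.065,
                         kappa = 0.25, tau_r = 10, tau_a = 1400,
                         tau_e = 70, tau_d = 3000, k_F = 12,
                         theta_F = 0.2, gamma = 0.075, tau_X = 100,
                         dt = 1) {
  p <- list(beta_e = beta_e, beta_i = beta_i, g = g, kappa = kappa,
            tau_r = tau_r, tau_a = tau_a, tau_e = tau_e, tau_d = tau_d,
            k_F = k_F, theta_F = theta_F, gamma = gamma, tau_X = tau_X,
            dt = dt)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("model parameter `", nm, "` must be a finite number")
  }
  for (nm in c("tau_r", "tau_a", "tau_e", "tau_d", "tau_X", "dt")) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be positive")
  }
  if (p$kappa < 0 || p$kappa > 1) stop("`kappa` must lie in [0, 1]")
  if (p$gamma < 0) stop("`gamma` must be non-negative")
  invisible(p)
}

#' Tonotopic input-stage parameters
#'
#' Parameters of the driving inputs: the auditory spread profile
#' `w(df) = M_a * exp(-df / sigma_a)`, the tactile spread profiles
#' `v(df) = M_t1 * exp(-df / sigma_t1)` (tactile pulses synchronized with a
#' single tone sequence) and `v(df) = M_t2 * exp(-df / sigma_t2)` (pulses
#' synchronized with both tone sequences), and the double alpha-function
#' pulse shape with onset timescale `alpha_1`, plateau timescale `alpha_2`
#' and peak-to-plateau ratio `Lambda_2`.
#'
#' @param M_a auditory spread amplitude (dimensionless).
#' @param sigma_a auditory spread decay constant, semitones.
#' @param M_t1 single-tone tactile amplitude.
#' @param sigma_t1 single-tone tactile decay constant, semitones.
#' @param M_t2 dual-tone tactile amplitude.
#' @param sigma_t2 dual-tone tactile decay constant, semitones.
#' @param alpha_1 pulse onset timescale, ms.
#' @param alpha_2 pulse plateau timescale, ms.
#' @param Lambda_2 peak-to-plateau ratio (dimensionless).
#' @return A named list of class `"input_params"`.
#' @seealso [alpha_input()], [auditory_weight()], [tactile_weight()],
#'   [build_inputs()]
#' @export
#' @examples
#' input_params()
#' input_params(M_t1 = 0.6)  # stronger single-tone tactile drive
input_params <- function(M_a = 0.95, sigma_a = 3.10, M_t1 = 0.45,
                         sigma_t1 = 1.2, M_t2 = 0.10, sigma_t2 = 18,
                         alpha_1 = 15, alpha_2 = 82.5, Lambda_2 = 1 / 6) {
  p <- list(M_a = M_a, sigma_a = sigma_a, M_t1 = M_t1, sigma_t1 = sigma_t1,
            M_t2 = M_t2, sigma_t2 = sigma_t2, alpha_1 = alpha_1,
            alpha_2 = alpha_2, Lambda_2 = Lambda_2)
  validate_input_params(p)
  structure(p, class = "input_params")
}

validate_input_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("input parameter `", nm, "` must be a finite number")
  }
  for (nm in c("M_a", "M_t1", "M_t2", "Lambda_2")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be non-negative")
  }
  for (nm in c("sigma_a", "sigma_t1", "sigma_t2", "alpha_1", "alpha_2")) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be positive")
  }
  invisible(p)
}

#' Specification of one ABA- trial
#'
#' Describes the stimulus of a single trial of the auditory streaming
#' paradigm: `n_triplets` repetitions of the ABA- triplet (A tone, B tone,
#' A tone, silence, each slot lasting one presentation period), with the A
#' tones `delta_f` semitones above the B tones, and tactile pulses
#' synchronized with the A tones only (`"A"`), the B tones only (`"B"`),
#' every tone (`"AB"`) or absent (`"off"`).
#'
#' Tone duration equals the presentation period (tone offsets align with the
#' next onset), so a triplet lasts `4 * presentation_period` ms.
#'
#' @param delta_f A-B frequency difference, semitones (>= 0).
#' @param tactile_condition one of `"off"`, `"A"`, `"B"`, `"AB"`.
#' @param tone_duration tone duration, ms.
#' @param presentation_period interval between successive tone onsets, ms.
#' @param n_triplets number of ABA- triplets per trial.
#' @param dt time-grid step, ms; must divide the presentation period.
#' @return A named list of class `"stimulus_spec"`.
#' @seealso [build_inputs()], [simulate_trial()]
#' @export
#' @examples
#' stimulus_spec(delta_f = 5)
#' stimulus_spec(delta_f = 4, tactile_condition = "B")
stimulus_spec <- function(delta_f, tactile_condition = c("off", "A", "B", "AB"),
                          tone_duration = 125, presentation_period = 125,
                          n_triplets = 5, dt = 1) {
  tactile_condition <- match.arg(tactile_condition)
  if (!is.numeric(delta_f) || length(delta_f) != 1L || !is.finite(delta_f) ||
      delta_f < 0) {
    stop("`delta_f` must be a single non-negative number (semitones)")
  }
  if (tone_duration <= 0 || presentation_period <= 0) {
    stop("durations must be positive")
  }
  if (n_triplets < 1 || n_triplets != round(n_triplets)) {
    stop("`n_triplets` must be a positive integer")
  }
  n_steps <- presentation_period / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("`dt` must divide the presentation period")
  }
  structure(list(delta_f = delta_f, tactile_condition = tactile_condition,
                 tone_duration = tone_duration,
                 presentation_period = presentation_period,
                 n_triplets = n_triplets, dt = dt),
            class = "stimulus_spec")
}

trial_duration <- function(spec) 4 * spec$presentation_period * spec$n_triplets

#' Read or write a parameter configuration
#'
#' Configurations are flat YAML or JSON maps keyed by the parameter names of
#' [model_params()], [input_params()] and [stimulus_spec()] (`M_a`, `sigma_a`,
#' `M_t1`, `sigma_t1`, `M_t2`, `sigma_t2`, `alpha_1`, `alpha_2`, `Lambda_2`,
#' `beta_e`, ..., `tone_duration`, `presentation_period`, `n_triplets`, ...).
#' Unknown keys are rejected. `read_config()` returns the three parameter
#' objects with file values overriding the defaults.
#'
#' @param path file path; format inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @param model,inputs,spec parameter objects to serialize (defaults used
#'   where omitted).
#' @return `read_config()`: a list with elements `model`, `inputs`, `spec`
#'   (`spec` is `NULL` unless the file sets `delta_f`). `write_config()`:
#'   the path, invisibly.
#' @export
read_config <- function(path) {
  values <- switch(tolower(tools::file_ext(path)),
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json")
  )
  if (!is.list(values)) stop("config must be a mapping of parameter values")
  mp_names <- names(formals(model_params))
  ip_names <- names(formals(input_params))
  sp_names <- setdiff(names(formals(stimulus_spec)), "dt")
  known <- unique(c(mp_names, ip_names, sp_names))
  bad <- setdiff(names(values), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  model <- do.call(model_params, values[intersect(names(values), mp_names)])
  inputs <- do.call(input_params, values[intersect(names(values), ip_names)])
  spec <- NULL
  if ("delta_f" %in% names(values)) {
    spec_args <- values[intersect(names(values), sp_names)]
    spec_args$dt <- model$dt
    spec <- do.call(stimulus_spec, spec_args)
  }
  list(model = model, inputs = inputs, spec = spec)
}

#' @rdname read_config
#' @export
write_config <- function(path, model = model_params(),
                         inputs = input_params(), spec = NULL) {
  values <- c(unclass(model), unclass(inputs))
  if (!is.null(spec)) values <- c(values, unclass(spec)[names(spec) != "dt"])
  switch(tolower(tools::file_ext(path)),
    "yaml" = , "yml" = yaml::write_yaml(values, path),
    "json" = jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA),
    stop("config must be .yaml, .yml or .json")
  )
  invisible(path)
}
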