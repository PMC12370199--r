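#' Classify a simulated trial as integrated or segregated
#'
#' Mirrors the behavioral report: the percept is read out over the final
#' triplet of the trial, the window `[(n_triplets - 1) * 4 PP,
#' n_triplets * 4 PP)`. The firing rates of the three units are averaged
#' over that window and the trial is `"segregated"` if a peripheral unit
#' dominates (`max(<r_A>, <r_B>) > <r_AB>`), `"integrated"` otherwise (ties
#' count as integrated). Set `variable = "e"` to classify on the slower
#' recurrent-excitation variables instead, and `window = "final_instant"`
#' to use the last sample only.
#'
#' @param trace a `"sim_trace"` from [simulate_trial()].
#' @param variable classify on firing rates (`"r"`, default) or recurrent
#'   excitation (`"e"`).
#' @param window `"final_triplet"` (default) or `"final_instant"`.
#' @return A list of class `"trial_outcome"`: `percept` (`"integrated"` or
#'   `"segregated"`), `window_means` (named means of the three units), and
#'   `seed`.
#' @export
classify_percept <- function(trace, variable = c("r", "e"),
                             window = c("final_triplet", "final_instant")) {
  variable <- match.arg(variable)
  window <- match.arg(window)
  spec <- trace$spec
  lo <- (spec$n_triplets - 1) * 4 * spec$presentation_period
  hi <- spec$n_triplets * 4 * spec$presentation_period
  idx <- which(trace$time >= lo & trace$time < hi)
  if (length(idx) == 0) stop("report window lies outside the trace")
  if (window == "final_instant") idx <- idx[length(idx)]
  cols <- paste0(variable, "_", c("A", "AB", "B"))
  m <- colMeans(trace$state[idx, cols, drop = FALSE])
  names(m) <- c("A", "AB", "B")
  percept <- if (max(m["A"], m["B"]) > m["AB"]) "segregated" else "integrated"
  structure(list(percept = percept, window_means = m, seed = trace$seed),
            class = "trial_outcome")
}

#' @exportS3Method base::print
print.trial_outcome <- function(x, ...) {
  cat("<trial_outcome> ", x$percept, " (<r_A> = ",
      signif(x$window_means["A"], 3), ", <r_AB> = ",
      signif(x$window_means["AB"], 3), ", <r_B> = ",
      signif(x$window_means["B"], 3), ")\n", sep = "")
  invisible(x)
}

# Monte-Carlo core shared by estimate_condition() and the fitting objective:
# returns the n_trials x 6 window-mean matrix (rA rAB rB eA eAB eB).
# Caller controls the RNG state.
run_trials <- function(spec, params, input_params, n_trials,
                       exact_ou = FALSE) {
  spec$dt <- params$dt
  inputs <- build_inputs(spec, input_params)
  lo <- (spec$n_triplets - 1) * 4 * spec$presentation_period
  hi <- spec$n_triplets * 4 * spec$presentation_period
  win_lo <- sum(inputs$time < lo)
  win_hi <- sum(inputs$time < hi)
  sim_trials_cpp(inputs$channels, params, params$dt, n_trials,
                 win_lo, win_hi, default_init_rates(), exact_ou)
}

segregated_from_means <- function(m, variable = "r") {
  off <- if (variable == "e") 3L else 0L
  pmax(m[, off + 1L], m[, off + 3L]) > m[, off + 2L]
}

#' Monte-Carlo estimate of the proportion segregated in one condition
#'
#' Runs `n_trials` independent trials of the stimulus described by `spec`
#' (fresh initial conditions and noise per trial, mirroring the
#' inter-trial gap of the behavioral paradigm), classifies each by
#' final-triplet dominance, and returns the proportion reported segregated
#' with its binomial standard error `sqrt(p (1 - p) / n)`.
#'
#' @param spec a [stimulus_spec()].
#' @param params a [model_params()] object.
#' @param input_params an [input_params()] object.
#' @param n_trials number of independent trials (>= 1).
#' @param seed integer seed; results are reproducible given the seed.
#' @param variable classification variable, `"r"` or `"e"` (see
#'   [classify_percept()]).
#' @param keep_trials attach the per-trial binary outcomes as a `responses`
#'   attribute column (list of 0/1 vectors) for record-level analyses.
#' @return A one-row data frame of class `"condition_estimate"`: `delta_f`,
#'   `condition`, `n`, `p_segregated`, `se`.
#' @export
#' @examples
#' \donttest{
#' estimate_condition(stimulus_spec(5), n_trials = 100, seed = 1)
#' }
estimate_condition <- function(spec, params = model_params(),
                               input_params = tactstream::input_params(),
                               n_trials = 500, seed = NULL,
                               variable = c("r", "e"), keep_trials = FALSE) {
  variable <- match.arg(variable)
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- run_trials(spec, params, input_params, n_trials)
  seg <- segregated_from_means(m, variable)
  p <- mean(seg)
  out <- data.frame(delta_f = spec$delta_f,
                    condition = spec$tactile_condition,
                    n = n_trials, p_segregated = p,
                    se = sqrt(p * (1 - p) / n_trials))
  if (keep_trials) out$responses <- I(list(as.integer(seg)))
  class(out) <- c("condition_estimate", "data.frame")
  out
}

#' Simulate an experimental condition grid
#'
#' Runs [estimate_condition()] over a full design: `design = "exp1"` crosses
#' frequency differences `{3, 4, 5, 6}` st with tactile conditions
#' `{off, B, AB}` (12 cells); `design = "exp2"` fixes `delta_f = 4` st and
#' crosses all four tactile conditions `{off, A, B, AB}`. A custom design is
#' given as a data frame with columns `delta_f` and `condition`.
#'
#' Each cell receives an independent seed derived from `seed`, so the grid
#' is reproducible and cells can be compared across parameter candidates
#' with common random numbers.
#'
#' @param design `"exp1"`, `"exp2"`, or a data frame with columns `delta_f`
#'   and `condition`.
#' @param params,input_params model and input parameters.
#' @param n_trials trials per cell.
#' @param seed integer master seed.
#' @param variable classification variable (`"r"` or `"e"`).
#' @param keep_trials keep per-trial binary outcomes (see
#'   [estimate_condition()]).
#' @return A data frame with one row per cell: `delta_f`, `condition`, `n`,
#'   `p_segregated`, `se` (plus `responses` if `keep_trials`).
#' @export
#' @examples
#' \donttest{
#' run_experiment_grid("exp2", n_trials = 100, seed = 1)
#' }
run_experiment_grid <- function(design = c("exp1", "exp2"),
                                params = model_params(),
                                input_params = tactstream::input_params(),
                                n_trials = 500, seed = NULL,
                                variable = c("r", "e"),
                                keep_trials = FALSE) {
  variable <- match.arg(variable)
  grid <- design_grid(design)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- stimulus_spec(grid$delta_f[i],
                          tactile_condition = grid$condition[i])
    cell_seed <- if (is.null(seed)) NULL else (seed + 1009L * i) %% 2147483647L
    rows[[i]] <- estimate_condition(spec, params, input_params, n_trials,
                                    seed = cell_seed, variable = variable,
                                    keep_trials = keep_trials)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

design_grid <- function(design) {
  if (is.data.frame(design)) {
    if (!all(c("delta_f", "condition") %in% names(design))) {
      stop("custom design needs columns `delta_f` and `condition`")
    }
    if (!all(design$condition %in% TACTILE_CONDITIONS)) {
      stop("unknown tactile condition in design")
    }
    return(design[c("delta_f", "condition")])
  }
  design <- match.arg(design, c("exp1", "exp2"))
  if (design == "exp1") {
    expand.grid(delta_f = c(3, 4, 5, 6), condition = c("off", "B", "AB"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(delta_f = 4, condition = c("off", "A", "B", "AB"))
  }
}
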