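default_bounds <- function(free) {
  amp <- c(0, 2)
  dec <- c(0.1, 50)
  is_amp <- grepl("^M_", free)
  list(lower = ifelse(is_amp, amp[1], dec[1]),
       upper = ifelse(is_amp, amp[2], dec[2]))
}

#' Mean-squared-error objective for spread-profile fitting
#'
#' Evaluates a candidate set of spread-profile parameters against an
#' observed proportion-segregated table: the observed grid is re-simulated
#' with the candidate values (all other parameters fixed) and the unweighted
#' mean over grid cells of `(p_obs - p_sim)^2` is returned.
#'
#' The simulation noise is controlled by `eval_seed`; using the same seed
#' for every candidate (common random numbers, the default inside
#' [fit_spread()]) makes the stochastic objective a smooth function of the
#' candidate.
#'
#' @param candidate named numeric vector of free-parameter values (names
#'   from [input_params()], e.g. `M_t1`, `sigma_t1`).
#' @param observed data frame with columns `delta_f`, `condition`,
#'   `p_segregated` (as produced by [run_experiment_grid()]).
#' @param params,input_params fixed model parameters and baseline input
#'   parameters; free entries of `input_params` are overridden by
#'   `candidate`.
#' @param n_trials trials per grid cell per evaluation.
#' @param eval_seed seed for the evaluation's simulations.
#' @return The mean squared error (single number).
#' @export
spread_objective <- function(candidate, observed, params = model_params(),
                             input_params = tactstream::input_params(),
                             n_trials = 300, eval_seed = 1L,
                             .cache = NULL, .noise = NULL) {
  if (is.null(names(candidate)) || !all(names(candidate) %in%
                                        names(input_params))) {
    stop("`candidate` must be named with input-parameter names")
  }
  if (any(!is.finite(candidate))) stop("non-finite candidate rejected")
  if (nrow(observed) == 0) stop("`observed` grid is empty")
  ip <- do.call(tactstream::input_params,
                modifyList(unclass(input_params), as.list(candidate)))
  if (is.null(.cache)) {
    sim <- run_experiment_grid(observed[c("delta_f", "condition")],
                               params = params, input_params = ip,
                               n_trials = n_trials, seed = eval_seed)
    p_sim <- sim$p_segregated
  } else {
    p_sim <- simulate_cached_grid(.cache, ip, params, n_trials, eval_seed,
                                  .noise = .noise)
  }
  mean((observed$p_segregated - p_sim)^2)
}

# The raw pulse trains do not depend on the spread parameters, so they are
# computed once per fit; objective evaluations then only redo the mixing.
# Seeding matches run_experiment_grid() exactly, which makes the cached and
# uncached objective bit-identical for spread-only candidates.
spread_cache <- function(observed, params, input_params) {
  lapply(seq_len(nrow(observed)), function(i) {
    spec <- stimulus_spec(observed$delta_f[i],
                          tactile_condition = observed$condition[i],
                          dt = params$dt)
    lo <- (spec$n_triplets - 1) * 4 * spec$presentation_period
    hi <- spec$n_triplets * 4 * spec$presentation_period
    trains <- pulse_trains(spec, input_params)
    list(spec = spec, trains = trains,
         win_lo = sum(trains$time < lo), win_hi = sum(trains$time < hi))
  })
}

simulate_cached_grid <- function(cache, ip, params, n_trials, eval_seed,
                                 .noise = NULL) {
  vapply(seq_along(cache), function(i) {
    cell <- cache[[i]]
    ch <- mix_channels(cell$trains, cell$spec, ip)
    m <- if (is.null(.noise)) {
      set.seed((eval_seed + 1009L * i) %% 2147483647L)
      sim_trials_cpp(ch, params, params$dt, n_trials,
                     cell$win_lo, cell$win_hi, default_init_rates(), FALSE)
    } else {
      sim_trials_frozen_cpp(ch, params, params$dt,
                            cell$win_lo, cell$win_hi, default_init_rates(),
                            .noise[[i]]$chi0, .noise[[i]]$z)
    }
    mean(segregated_from_means(m))
  }, numeric(1))
}

# One frozen noise realization per grid cell: initial values from the
# stationary law plus all standard-normal increments for n_trials trials.
frozen_noise <- function(cache, params, n_trials, seed) {
  set.seed(seed)
  lapply(cache, function(cell) {
    n_steps <- length(cell$trains$time)
    list(chi0 = rnorm(3 * n_trials, 0, params$gamma),
         z = rnorm(3 * n_trials * (n_steps - 1)))
  })
}

# Classic differential evolution (rand/1/bin) over a box. Deterministic
# given the RNG state on entry. Returns the best member and its value.
de_optim <- function(fn, lower, upper, n_pop = 16L, n_gen = 25L,
                     f_weight = 0.8, cr = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  pop <- matrix(runif(n_pop * d, lower, upper), nrow = n_pop, byrow = TRUE)
  fit <- apply(pop, 1, fn)
  for (gen in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3L)
      trial <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      f_trial <- fn(trial)
      if (f_trial <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best],
       n_eval = n_pop * (n_gen + 1L))
}

#' Fit spread-profile parameters to proportion-segregated data
#'
#' Global box-bounded fit of a subset of the input-stage spread parameters
#' (`M_a`, `sigma_a`, `M_t1`, `sigma_t1`, `M_t2`, `sigma_t2`) to an observed
#' condition-grid table, minimizing [spread_objective()] by differential
#' evolution. The whole procedure is repeated `n_repeats` times from
#' independent random starts, and the spread (sample sd) of the per-repeat
#' estimates quantifies fit uncertainty; the reported point estimate is the
#' repeat with the lowest achieved objective.
#'
#' Default bounds are `[0, 2]` for amplitudes and `[0.1, 50]` st for decay
#' constants. By default every objective evaluation within one repeat reuses
#' the same simulation seed (common random numbers), which smooths the
#' Monte-Carlo objective; `fresh_seeds = TRUE` redraws noise per evaluation.
#'
#' @param observed data frame with columns `delta_f`, `condition`,
#'   `p_segregated`.
#' @param free names of the parameters to fit.
#' @param lower,upper optional named bounds (defaults above).
#' @param params,input_params fixed model parameters and baseline inputs.
#' @param n_trials trials per grid cell per objective evaluation.
#' @param n_repeats independent optimizer repeats.
#' @param n_pop,n_gen differential-evolution population size and number of
#'   generations.
#' @param seed master seed (drives starts, evolution, and evaluation seeds).
#' @param fresh_seeds redraw simulation noise at every evaluation instead of
#'   common random numbers.
#' @return An object of class `"fit_result"`: `estimate` (named vector, best
#'   repeat), `objective` (its achieved MSE), `repeats` (data frame of
#'   per-repeat estimates and objectives), `center` and `spread` (mean and
#'   sample sd over repeats), plus the settings used.
#' @export
fit_spread <- function(observed,
                       free = c("M_t1", "sigma_t1", "M_t2", "sigma_t2"),
                       lower = NULL, upper = NULL,
                       params = model_params(),
                       input_params = tactstream::input_params(),
                       n_trials = 300, n_repeats = 20, n_pop = 16L,
                       n_gen = 25L, seed = 1L, fresh_seeds = FALSE) {
  if (length(free) == 0) stop("`free` must name at least one parameter")
  if (!all(free %in% names(input_params))) stop("unknown free parameter")
  bounds <- default_bounds(free)
  lo <- setNames(bounds$lower, free)
  up <- setNames(bounds$upper, free)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(up)) || any(up < lo)) {
    stop("bounds must be finite with upper >= lower")
  }
  spread_names <- c("M_a", "sigma_a", "M_t1", "sigma_t1", "M_t2", "sigma_t2")
  cache <- if (all(free %in% spread_names)) {
    spread_cache(observed, params, input_params)
  }
  reps <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rep_seed <- (seed + 7919L * r) %% 2147483647L
    noise <- if (!is.null(cache) && !fresh_seeds) {
      # freeze this repeat's noise paths: every candidate is evaluated on
      # the identical realization, making the objective deterministic
      frozen_noise(cache, params, n_trials, rep_seed)
    }
    set.seed(rep_seed)
    eval_counter <- 0L
    fn <- function(x) {
      if (!is.null(noise)) {
        return(spread_objective(setNames(x, free), observed, params,
                                input_params, n_trials, rep_seed,
                                .cache = cache, .noise = noise))
      }
      eval_seed <- if (fresh_seeds) {
        eval_counter <<- eval_counter + 1L
        (rep_seed + eval_counter) %% 2147483647L
      } else {
        rep_seed
      }
      rng <- get(".Random.seed", envir = globalenv())
      val <- spread_objective(setNames(x, free), observed, params,
                              input_params, n_trials, eval_seed,
                              .cache = cache)
      # objective sims must not perturb DE's own stream
      assign(".Random.seed", rng, envir = globalenv())
      val
    }
    res <- de_optim(fn, lo, up, n_pop = n_pop, n_gen = n_gen)
    reps[[r]] <- c(setNames(res$par, free), objective = res$value)
  }
  rep_tab <- as.data.frame(do.call(rbind, reps))
  rep_tab$repeat_id <- seq_len(n_repeats)
  best <- which.min(rep_tab$objective)
  est <- unlist(rep_tab[best, free, drop = FALSE])
  structure(list(estimate = setNames(as.numeric(est), free),
                 objective = rep_tab$objective[best],
                 repeats = rep_tab,
                 center = colMeans(rep_tab[, free, drop = FALSE]),
                 spread = vapply(rep_tab[, free, drop = FALSE], sd,
                                 numeric(1)),
                 free = free, lower = lo, upper = up,
                 n_trials = n_trials, n_pop = n_pop, n_gen = n_gen,
                 seed = seed, fresh_seeds = fresh_seeds),
            class = "fit_result")
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", length(x$free), " free parameter(s), ",
      nrow(x$repeats), " repeat(s), best MSE = ",
      signif(x$objective, 4), "\n", sep = "")
  tab <- data.frame(estimate = x$estimate, center = x$center,
                    spread = x$spread, lower = x$lower, upper = x$upper)
  print(signif(tab, 4))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes the point estimates, per-repeat table and full provenance
#' (bounds, seeds, optimizer settings) of a [fit_spread()] result.
#'
#' @param x a `"fit_result"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
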