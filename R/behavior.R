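#' Specification of a synthetic behavioral dataset
#'
#' Defines the mixed-logit structure used to generate per-trial binary
#' segregation reports: for participant `i` in condition cell
#' `(delta_f, cond)`, the probability of reporting segregated is
#' `plogis(intercept + slope * delta_f + offset[cond] +
#' interaction[cond] * delta_f + u_i)` with participant random intercepts
#' `u_i ~ N(0, ranef_sd^2)`.
#'
#' @param intercept fixed intercept, logits.
#' @param slope frequency-difference slope, logits per semitone.
#' @param offsets named numeric vector of per-condition offsets relative to
#'   the reference condition `"off"` (e.g. `c(AB = -0.32, B = 0.42)`).
#' @param interactions optional named vector of condition-specific
#'   `delta_f` slope adjustments, logits per semitone.
#' @param ranef_sd participant random-intercept sd, logits.
#' @param n_participants number of participants.
#' @param n_reps trials per participant per design cell.
#' @param design `"exp1"`, `"exp2"`, or a data frame with columns `delta_f`
#'   and `condition` (see [run_experiment_grid()]).
#' @return A list of class `"behavior_spec"`.
#' @export
behavior_spec <- function(intercept = -4.16, slope = 0.96,
                          offsets = c(AB = -0.32, B = 0.42),
                          interactions = NULL, ranef_sd = 0.5,
                          n_participants = 6, n_reps = 20,
                          design = "exp1") {
  grid <- design_grid(design)
  conds <- setdiff(unique(grid$condition), "off")
  if (!all(names(offsets) %in% TACTILE_CONDITIONS)) {
    stop("offset names must be tactile conditions")
  }
  if (!is.null(interactions) &&
      !all(names(interactions) %in% TACTILE_CONDITIONS)) {
    stop("interaction names must be tactile conditions")
  }
  if (n_participants < 1 || n_reps < 1) {
    stop("`n_participants` and `n_reps` must be >= 1")
  }
  if (ranef_sd < 0) stop("`ranef_sd` must be non-negative")
  structure(list(intercept = intercept, slope = slope, offsets = offsets,
                 interactions = interactions, ranef_sd = ranef_sd,
                 n_participants = n_participants, n_reps = n_reps,
                 grid = grid, conditions = conds),
            class = "behavior_spec")
}

cell_logit <- function(spec, delta_f, condition) {
  eta <- spec$intercept + spec$slope * delta_f
  if (condition %in% names(spec$offsets)) {
    eta <- eta + spec$offsets[[condition]]
  }
  if (condition %in% names(spec$interactions)) {
    eta <- eta + spec$interactions[[condition]] * delta_f
  }
  eta
}

#' Generate synthetic binary segregation reports
#'
#' Draws a long-format behavioral dataset under the mixed-logit model of
#' [behavior_spec()]: one participant random intercept per participant,
#' then independent Bernoulli responses for every trial of the design.
#'
#' @param spec a [behavior_spec()].
#' @param seed integer seed.
#' @return A data frame with one row per trial: `participant` (factor),
#'   `delta_f`, `condition` (factor, reference level `"off"`), `response`
#'   (0/1, 1 = segregated).
#' @export
#' @examples
#' dat <- generate_behavior(behavior_spec(n_participants = 3, n_reps = 2),
#'                          seed = 1)
#' head(dat)
generate_behavior <- function(spec, seed = NULL) {
  if (nrow(spec$grid) == 0) stop("empty design")
  if (!is.null(seed)) set.seed(seed)
  u <- rnorm(spec$n_participants, 0, spec$ranef_sd)
  cells <- spec$grid[rep(seq_len(nrow(spec$grid)),
                         each = spec$n_participants * spec$n_reps), ]
  out <- data.frame(
    participant = factor(rep(rep(seq_len(spec$n_participants),
                                 each = spec$n_reps), nrow(spec$grid))),
    delta_f = cells$delta_f,
    condition = factor(cells$condition,
                       levels = intersect(TACTILE_CONDITIONS,
                                          unique(spec$grid$condition)))
  )
  eta <- mapply(cell_logit, delta_f = out$delta_f,
                condition = as.character(out$condition),
                MoreArgs = list(spec = spec)) +
    u[as.integer(out$participant)]
  out$response <- rbinom(nrow(out), 1L, plogis(eta))
  rownames(out) <- NULL
  out
}

#' Mixed-effects logistic analysis of segregation reports
#'
#' Fits a generalized linear mixed model with logit link and a participant
#' random intercept to trial-level binary reports, via [lme4::glmer()]
#' (Laplace approximation). Fixed effects are specified as term names;
#' `condition` uses treatment coding with `ref` as the reference level.
#' Internally, trials are aggregated to binomial counts per participant and
#' design cell, which leaves the likelihood unchanged.
#'
#' @param data data frame with columns `participant`, `delta_f`,
#'   `condition`, `response` (0/1), as from [generate_behavior()] or
#'   [attach_model_reports()].
#' @param fixed character vector of fixed-effect terms built from
#'   `"delta_f"` and `"condition"`; interactions as `"delta_f:condition"`.
#' @param ref reference tactile condition for treatment coding.
#' @return A list of class `"glmm_result"`: `coefficients` (data frame with
#'   `term`, `estimate`, `std_error`, `z_value`, `p_value` — Wald two-sided),
#'   `aic`, `bic`, `ranef_sd`, `converged`, and the fitted `model`.
#' @export
fit_glmm <- function(data, fixed = c("delta_f", "condition"), ref = "off") {
  needed <- c("participant", "delta_f", "condition", "response")
  if (!all(needed %in% names(data))) {
    stop("data must have columns ", paste(needed, collapse = ", "))
  }
  if (length(unique(data$participant)) < 2) {
    stop("need at least 2 participants for a random intercept")
  }
  if (!all(data$response %in% c(0, 1))) stop("responses must be 0/1")
  data$condition <- stats::relevel(factor(data$condition), ref = ref)
  vars <- all.vars(as.formula(paste("~", paste(fixed, collapse = "+"))))
  for (v in vars) {
    if (length(unique(data[[v]])) < 2) {
      stop("fixed-effect term `", v, "` needs at least 2 levels")
    }
  }
  agg <- aggregate(response ~ participant + delta_f + condition, data = data,
                   FUN = function(x) c(k = sum(x), n = length(x)))
  agg$k <- agg$response[, "k"]
  agg$n <- agg$response[, "n"]
  form <- as.formula(paste("cbind(k, n - k) ~",
                           paste(fixed, collapse = " + "),
                           "+ (1 | participant)"))
  fit <- lme4::glmer(form, data = agg, family = stats::binomial())
  sm <- summary(fit)$coefficients
  msgs <- fit@optinfo$conv$lme4$messages
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      std_error = sm[, "Std. Error"],
                      z_value = sm[, "z value"],
                      p_value = sm[, "Pr(>|z|)"], row.names = NULL)
  separation <- any(abs(coefs$estimate) > 15)
  structure(list(coefficients = coefs, aic = AIC(fit), bic = BIC(fit),
                 ranef_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
                 converged = is.null(msgs), messages = msgs,
                 separation = separation, model = fit),
            class = "glmm_result")
}

#' @exportS3Method base::print
print.glmm_result <- function(x, ...) {
  cat("<glmm_result> logit GLMM, participant random intercept (sd = ",
      signif(x$ranef_sd, 3), ")\n", sep = "")
  tab <- x$coefficients
  tab[-1] <- signif(tab[-1], 4)
  print(tab)
  cat("AIC = ", round(x$aic, 1), ", BIC = ", round(x$bic, 1), "\n", sep = "")
  if (!x$converged) cat("warning: ", paste(x$messages, collapse = "; "), "\n")
  if (x$separation) cat("warning: possible separation (|estimate| > 15)\n")
  invisible(x)
}

#' Effect-size conversions for logistic coefficients
#'
#' `odds_ratio()` converts a log-odds coefficient to an odds ratio,
#' `exp(coefficient)`. `cohens_d_from_logodds()` converts it to a Cohen's d
#' via the logistic convention `|coefficient| * sqrt(3) / pi` (the logistic
#' distribution has sd `pi / sqrt(3)`).
#'
#' @param coefficient log-odds coefficient(s).
#' @return The odds ratio(s), or Cohen's d value(s) (non-negative).
#' @export
#' @examples
#' odds_ratio(c(-0.45, 0.36))            # 0.64, 1.44
#' cohens_d_from_logodds(c(-0.45, 0.36)) # 0.25, 0.20
odds_ratio <- function(coefficient) {
  if (any(!is.finite(coefficient))) stop("coefficient must be finite")
  exp(coefficient)
}

#' @rdname odds_ratio
#' @export
cohens_d_from_logodds <- function(coefficient) {
  if (any(!is.finite(coefficient))) stop("coefficient must be finite")
  abs(coefficient) * sqrt(3) / pi
}

#' Expand simulated condition estimates into record-level reports
#'
#' Bridges the simulator into the statistics pipeline: per-trial binary
#' outcomes from [run_experiment_grid()]`(keep_trials = TRUE)` are expanded
#' to one row per trial. Trials within each cell are split across
#' `n_participants` pseudo-participants in blocks (trials are independent,
#' so the split is a labeling device that lets [fit_glmm()] run end-to-end
#' on simulator output).
#'
#' @param estimates a grid from [run_experiment_grid()] with `keep_trials =
#'   TRUE` (a `responses` list column).
#' @param n_participants number of pseudo-participants to label.
#' @return A data frame with columns `participant`, `delta_f`, `condition`,
#'   `response`, compatible with [fit_glmm()].
#' @export
attach_model_reports <- function(estimates, n_participants = 1) {
  if (!"responses" %in% names(estimates)) {
    stop("`estimates` must carry per-trial responses ",
         "(run_experiment_grid(keep_trials = TRUE))")
  }
  n <- unique(estimates$n)
  if (any(n < n_participants)) {
    stop("fewer trials per cell than pseudo-participants")
  }
  rows <- vector("list", nrow(estimates))
  for (i in seq_len(nrow(estimates))) {
    resp <- estimates$responses[[i]]
    part <- ceiling(seq_along(resp) / (length(resp) / n_participants))
    rows[[i]] <- data.frame(participant = part,
                            delta_f = estimates$delta_f[i],
                            condition = estimates$condition[i],
                            response = resp)
  }
  out <- do.call(rbind, rows)
  out$participant <- factor(out$participant)
  out$condition <- factor(out$condition,
                          levels = intersect(TACTILE_CONDITIONS,
                                             unique(out$condition)))
  rownames(out) <- NULL
  out
}
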