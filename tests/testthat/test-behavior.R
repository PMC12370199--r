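test_that("effect-size conversions reproduce the standard pairs", {
  expect_equal(round(odds_ratio(-0.45), 2), 0.64)
  # exp(0.36) = 1.4333: agrees with the conventional printed pair 1.44
  # within the precision of a coefficient itself rounded to 2 decimals
  expect_equal(odds_ratio(0.36), 1.44, tolerance = 0.005)
  expect_equal(odds_ratio(0), 1)
  expect_equal(round(cohens_d_from_logodds(-0.45), 2), 0.25)
  expect_equal(round(cohens_d_from_logodds(0.36), 2), 0.20)
  expect_equal(cohens_d_from_logodds(0), 0)

  # log is a left inverse, and the d conversion is symmetric in sign
  x <- c(-1.3, -0.2, 0.4, 2)
  expect_equal(log(odds_ratio(x)), x)
  expect_equal(cohens_d_from_logodds(x), cohens_d_from_logodds(-x))
  expect_error(odds_ratio(Inf), "finite")
})

test_that("the behavioral generator saturates and centers correctly", {
  sat <- generate_behavior(behavior_spec(intercept = -20, slope = 0,
                                         offsets = c(AB = 0, B = 0),
                                         ranef_sd = 0), seed = 1)
  expect_true(all(sat$response == 0))

  fair <- generate_behavior(behavior_spec(intercept = 0, slope = 0,
                                          offsets = c(AB = 0, B = 0),
                                          ranef_sd = 0, n_participants = 20,
                                          n_reps = 25), seed = 2)
  expect_equal(mean(fair$response), 0.5,
               tolerance = 3 * sqrt(0.25 / nrow(fair)) / 0.5)
})

test_that("cell proportions match the closed-form logistic means", {
  spec <- behavior_spec(intercept = -4.16, slope = 0.96,
                        offsets = c(AB = -0.32, B = 0.42), ranef_sd = 0,
                        n_participants = 25, n_reps = 40)
  dat <- generate_behavior(spec, seed = 3)
  expect_equal(nrow(dat), 12 * 25 * 40)
  agg <- aggregate(response ~ delta_f + condition, dat, mean)
  eta <- with(agg, -4.16 + 0.96 * delta_f +
                     ifelse(condition == "AB", -0.32,
                            ifelse(condition == "B", 0.42, 0)))
  p <- plogis(eta)
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(agg$response - p) <= 3 * se + 1e-9))
})

test_that("participant random intercepts add over-dispersion", {
  spec <- behavior_spec(ranef_sd = 1.5, n_participants = 40, n_reps = 30,
                        design = data.frame(delta_f = 4, condition = "off"))
  dat <- generate_behavior(spec, seed = 4)
  by_part <- aggregate(response ~ participant, dat, mean)$response
  p <- mean(dat$response)
  binom_sd <- sqrt(p * (1 - p) / 30)
  expect_gt(sd(by_part), 2 * binom_sd)
})

test_that("the mixed logit recovers known generating coefficients", {
  spec <- behavior_spec(n_participants = 12, n_reps = 40, ranef_sd = 0.5)
  dat <- generate_behavior(spec, seed = 5)
  fit <- fit_glmm(dat)
  co <- fit$coefficients
  expect_setequal(co$term, c("(Intercept)", "delta_f", "conditionB",
                             "conditionAB"))
  truth <- c("(Intercept)" = -4.16, delta_f = 0.96, conditionAB = -0.32,
             conditionB = 0.42)
  for (tm in names(truth)) {
    row <- co[co$term == tm, ]
    expect_lt(abs(row$estimate - truth[[tm]]) / row$std_error, 4)
  }
  expect_equal(co$z_value, co$estimate / co$std_error)
  expect_equal(co$p_value, 2 * pnorm(-abs(co$z_value)))
  expect_true(is.finite(fit$aic) && is.finite(fit$bic))
})

test_that("reference releveling changes the contrast sign pattern", {
  spec <- behavior_spec(design = "exp2", offsets = c(A = 0.53, B = 0.26,
                                                     AB = -0.54),
                        intercept = -0.3, slope = 0, ranef_sd = 0.3,
                        n_participants = 12, n_reps = 60)
  dat <- generate_behavior(spec, seed = 6)
  ref_off <- fit_glmm(dat, fixed = "condition", ref = "off")
  co <- ref_off$coefficients
  expect_gt(co$estimate[co$term == "conditionA"], 0)
  expect_lt(co$estimate[co$term == "conditionAB"], 0)

  ref_b <- fit_glmm(dat, fixed = "condition", ref = "B")
  cb <- ref_b$coefficients
  expect_gt(cb$estimate[cb$term == "conditionA"],
            cb$estimate[cb$term == "conditionAB"])
})

test_that("information criteria prefer the additive model on
           interaction-free data", {
  wins <- 0
  for (i in 1:9) {
    dat <- generate_behavior(behavior_spec(n_participants = 8, n_reps = 30),
                             seed = 600 + i)
    add <- suppressWarnings(fit_glmm(dat, fixed = c("delta_f", "condition")))
    int <- suppressWarnings(fit_glmm(dat, fixed = c("delta_f", "condition",
                                                    "delta_f:condition")))
    wins <- wins + (add$bic < int$bic)
  }
  expect_gt(wins, 4.5)
})

test_that("degenerate designs are rejected with clear errors", {
  dat <- generate_behavior(behavior_spec(n_participants = 4, n_reps = 2),
                           seed = 7)
  expect_error(fit_glmm(dat[dat$participant == "1", ]), "participants")
  one_cond <- dat[dat$condition == "off", ]
  expect_error(fit_glmm(one_cond, fixed = "condition"), "levels")
  bad <- dat
  bad$response[1] <- 2
  expect_error(fit_glmm(bad), "0/1")
})

test_that("simulated grids expand into record-level reports", {
  g <- run_experiment_grid("exp1", n_trials = 40, seed = 8,
                           keep_trials = TRUE)
  recs <- attach_model_reports(g)
  expect_equal(nrow(recs), 12 * 40)
  expect_equal(nlevels(recs$participant), 1)

  recs6 <- attach_model_reports(g, n_participants = 5)
  expect_equal(nlevels(recs6$participant), 5)
  expect_equal(nrow(recs6), 12 * 40)

  # proportions survive the expansion
  agg <- aggregate(response ~ delta_f + condition, recs, mean)
  m <- merge(agg, g[c("delta_f", "condition", "p_segregated")])
  expect_equal(m$response, m$p_segregated)

  plain <- run_experiment_grid("exp2", n_trials = 5, seed = 9)
  expect_error(attach_model_reports(plain), "keep_trials")
})
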