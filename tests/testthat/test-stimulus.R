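test_that("double alpha-function pulse has the documented shape", {
  expect_equal(alpha_input(-5), 0)
  expect_equal(alpha_input(0), 0)

  # first-component peak equals 1 at t = alpha_1, for any alpha_1
  for (a1 in c(5, 15, 40)) {
    p <- input_params(alpha_1 = a1, Lambda_2 = 0)
    expect_equal(alpha_input(a1, p), 1)
    near <- alpha_input(a1 + c(-1, 1), p)
    expect_true(all(near < 1))
  }

  # independent high-precision evaluation of the full form at the plateau
  # timescale (both components active)
  expect_equal(alpha_input(82.5), 0.170399813240289, tolerance = 1e-12)

  # non-negative and continuous across the onset
  tt <- seq(-10, 600, by = 0.25)
  v <- alpha_input(tt)
  expect_true(all(v >= 0))
  expect_lt(max(abs(diff(v))), 0.05)
})

test_that("tonotopic spread profiles are exponential decays", {
  p <- input_params()
  expect_equal(auditory_weight(0, p), 0.95)
  expect_equal(auditory_weight(3.10, p), 0.349485469112870, tolerance = 1e-12)
  expect_equal(tactile_weight(0, "single", p), 0.45)
  expect_equal(tactile_weight(0, "dual", p), 0.10)
  expect_equal(tactile_weight(18, "dual", p), 0.0367879441171442,
               tolerance = 1e-12)

  df <- seq(0, 20, by = 0.5)
  expect_true(all(diff(auditory_weight(df, p)) < 0))
  expect_lt(auditory_weight(60, p), 1e-8)

  expect_error(auditory_weight(-1, p), "non-negative")
  expect_error(tactile_weight(1, "both", p))
})

test_that("onset schedule follows the ABA- paradigm and tactile condition", {
  sB <- onset_schedule(stimulus_spec(4, "B", n_triplets = 1))
  expect_equal(sB$A, c(0, 250))
  expect_equal(sB$B, 125)
  expect_equal(sB$tact_A, numeric(0))
  expect_equal(sB$tact_B, 125)

  sA <- onset_schedule(stimulus_spec(4, "A", n_triplets = 1))
  expect_equal(sA$tact_A, c(0, 250))
  expect_equal(sA$tact_B, numeric(0))

  s2 <- onset_schedule(stimulus_spec(4, "off", n_triplets = 2))
  expect_equal(s2$A, c(0, 250, 500, 750))
  expect_equal(s2$B, c(125, 625))
  expect_length(c(s2$tact_A, s2$tact_B), 0)

  # condition A has twice as many tactile pulses per triplet as condition B
  sAB <- onset_schedule(stimulus_spec(4, "AB", n_triplets = 3))
  expect_length(sAB$tact_A, 6)
  expect_length(sAB$tact_B, 3)
})

test_that("input channels mix tone and tactile trains by the spread matrix", {
  p <- input_params()

  off <- build_inputs(stimulus_spec(4, "off"), p)
  expect_true(all(off$channels[, c("t_A", "t_AB", "t_B")] == 0))
  expect_true(all(off$channels >= 0))

  # at zero frequency difference the two peripheral channels coincide
  z <- build_inputs(stimulus_spec(0, "off"), p)
  expect_equal(z$channels[, "i_A"], z$channels[, "i_B"])

  # channels reproduce the mixing formula applied to the raw pulse trains
  spec <- stimulus_spec(4, "AB")
  inp <- build_inputs(spec, p)
  sched <- onset_schedule(spec)
  I_A <- rowSums(sapply(sched$A, function(on) alpha_input(inp$time - on, p)))
  I_B <- rowSums(sapply(sched$B, function(on) alpha_input(inp$time - on, p)))
  expect_equal(inp$channels[, "i_AB"],
               auditory_weight(2, p) * (I_A + I_B), ignore_attr = TRUE)
  expect_equal(inp$channels[, "i_A"],
               0.95 * I_A + auditory_weight(4, p) * I_B, ignore_attr = TRUE)
  expect_equal(inp$channels[, "t_AB"],
               tactile_weight(2, "dual", p) * (I_A + I_B),
               ignore_attr = TRUE)

  # at an instant where both pulse trains equal 1, the central channel
  # equals 2 * w(df/2); independently evaluated for df = 4
  expect_equal(2 * auditory_weight(2, p), 0.996698059285997,
               tolerance = 1e-12)

  # extending the trial leaves the earlier samples untouched
  short <- build_inputs(stimulus_spec(4, "B", n_triplets = 2), p)
  long <- build_inputs(stimulus_spec(4, "B", n_triplets = 4), p)
  n <- length(short$time)
  expect_equal(long$channels[seq_len(n), ], short$channels)

  expect_error(stimulus_spec(4, dt = 30), "divide")
  expect_error(stimulus_spec(-1), "non-negative")
})

test_that("tactile mixing uses single-mode weights for A/B, dual for AB", {
  p <- input_params()
  one <- build_inputs(stimulus_spec(6, "B", n_triplets = 1), p)
  sched <- onset_schedule(stimulus_spec(6, "B", n_triplets = 1))
  T_B <- alpha_input(one$time - sched$tact_B, p)
  expect_equal(one$channels[, "t_B"], 0.45 * T_B, ignore_attr = TRUE)
  expect_equal(one$channels[, "t_A"],
               tactile_weight(6, "single", p) * T_B, ignore_attr = TRUE)

  both <- build_inputs(stimulus_spec(6, "AB", n_triplets = 1), p)
  sab <- onset_schedule(stimulus_spec(6, "AB", n_triplets = 1))
  T_Ad <- rowSums(sapply(sab$tact_A,
                         function(on) alpha_input(both$time - on, p)))
  T_Bd <- alpha_input(both$time - sab$tact_B, p)
  expect_equal(both$channels[, "t_B"],
               tactile_weight(6, "dual", p) * T_Ad + 0.10 * T_Bd,
               ignore_attr = TRUE)
})

test_that("input series exports to tidy long format", {
  inp <- build_inputs(stimulus_spec(3, "B", n_triplets = 1))
  df <- as.data.frame(inp)
  expect_named(df, c("time_ms", "channel", "value"))
  expect_equal(nrow(df), 6 * length(inp$time))
  expect_setequal(unique(df$channel),
                  c("i_A", "i_AB", "i_B", "t_A", "t_AB", "t_B"))
})

test_that("parameter configs round-trip through YAML and JSON", {
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_config(path, model = model_params(gamma = 0.1),
                 inputs = input_params(M_t1 = 0.5),
                 spec = stimulus_spec(4, "B"))
    got <- read_config(path)
    expect_equal(got$model$gamma, 0.1)
    expect_equal(got$inputs$M_t1, 0.5)
    expect_equal(got$inputs$sigma_t2, 18)
    expect_equal(got$spec$delta_f, 4)
    expect_equal(got$spec$tactile_condition, "B")
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(M_a = 1, nonsense = 2), bad)
  expect_error(read_config(bad), "unknown config keys")
})
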