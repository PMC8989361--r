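test_that("replay on the steady fixture is deterministic and fully logged", {
  s <- builtin_series("steady")
  cfg <- quiet_cfg()
  r1 <- replay(s, config = cfg)
  r2 <- replay(s, config = cfg)
  expect_identical(r1$trigger_year, r2$trigger_year)
  expect_identical(r1$yearly_log, r2$yearly_log)
  expect_equal(r1$outcome, "triggered")
  expect_equal(r1$n_failures_at_trigger,
               r1$trigger_year - s$year[1])  # one failure per elapsed year
  # the log covers every decision year from the fit window to the trigger
  expect_equal(r1$yearly_log$year,
               seq(s$year[cfg$fit_window], r1$trigger_year))
  expect_true(all(r1$yearly_log$action[-nrow(r1$yearly_log)] == "in_situ"))
  expect_equal(r1$yearly_log$action[nrow(r1$yearly_log)], "ex_situ")
  # w1 calibrated from the first observed abundance
  expect_equal(r1$w1_used, log(20) / s$abundance[1])
})

test_that("replay errors on series shorter than the fit window", {
  expect_error(replay(abundance_series(2000:2001, c(10, 8)), config = quiet_cfg()),
               "insufficient data|yearly")
})

test_that("certain undiscounted capture triggers at the first decision year", {
  s <- builtin_series("steady")
  res <- replay(s, value_params(w2 = 1, px = 1), quiet_cfg())
  expect_equal(res$trigger_year, s$year[3])  # fit window = 3 observations
  expect_equal(res$n_failures_at_trigger, 2L)
})

test_that("worthless capture never triggers and extinction is logged", {
  res <- replay(builtin_series("steady"), value_params(px = 0), quiet_cfg())
  expect_equal(res$outcome, "end_of_series")
  expect_true(is.na(res$trigger_year))
  expect_true(all(res$yearly_log$action == "in_situ"))

  s0 <- builtin_series("steady_to_zero")
  expect_true(any(s0$abundance == 0))
  res0 <- replay(s0, value_params(px = 0), quiet_cfg())
  expect_equal(res0$outcome, "extinct")
  expect_true(is.na(res0$trigger_year))
  expect_equal(res0$extinction_year, s0$year[which(s0$abundance == 0)[1]])
})

test_that("a recovery upturn postpones the trigger relative to the paired decline", {
  cfg <- quiet_cfg()
  postponed <- 0L
  for (seed in c(103L, 7L, 21L)) {
    sp_up <- scenario_spec(N0 = 250, slope = -12, noise_sd = 8, n_years = 20,
                           recovery_year = 5, seed = seed, start_year = 1980)
    sp_no <- scenario_spec(N0 = 250, slope = -12, noise_sd = 8, n_years = 20,
                           seed = seed, start_year = 1980)
    r_up <- trigger_rel(replay(generate_series(sp_up), config = cfg), 1980)
    r_no <- trigger_rel(replay(generate_series(sp_no), config = cfg), 1980)
    expect_gte(r_up, r_no)
    if (r_up > r_no) postponed <- postponed + 1L
  }
  expect_gte(postponed, 2L)  # strict postponement in most paired draws
})

test_that("observations after the trigger year do not change the decision", {
  s <- builtin_series("steady")
  cfg <- quiet_cfg()
  full <- replay(s, config = cfg)
  cut_idx <- which(s$year == full$trigger_year)
  truncated <- replay(s[seq_len(cut_idx)], config = cfg)
  expect_equal(truncated$trigger_year, full$trigger_year)
  expect_equal(truncated$yearly_log$value, full$yearly_log$value)
})

test_that("forecast band degenerates to the fitted line when the slope is exact", {
  m <- make_model(-5, 0, 100)
  fb <- forecast_band(m, horizon = 10)
  expect_equal(fb$lower, fb$upper)
  expect_equal(fb$fit, pmax(0, 100 - 5 * (1:10)))
})

test_that("forecast band widens linearly with lead time for a normal slope", {
  m <- make_model(-5, 1.2, 100)
  fb <- forecast_band(m, horizon = 8)
  width <- fb$upper - fb$lower
  expect_equal(width, width[1] * (1:8), tolerance = 1e-10)
  expect_error(forecast_band(m, horizon = 5, level = 1.2), "level")
})

test_that("the 95% band covers the true deterministic trajectory", {
  # simulate noisy observed declines; check the band covers the true
  # (noise-free) future trend at a 5-year lead
  covered <- 0L
  n_reps <- 200L
  for (seed in seq_len(n_reps)) {
    sp <- scenario_spec(N0 = 200, slope = -8, noise_sd = 10, n_years = 12,
                        seed = seed)
    s <- generate_series(sp)
    m <- fit_decline(s)
    fb <- forecast_band(m, horizon = 5)
    truth <- pmax(0, 200 - 8 * (11 + fb$year_ahead))
    # recentre on the true trend at the reference year to isolate slope error
    shift <- s$abundance[12] - (200 - 8 * 11)
    covered <- covered + all(truth + shift >= fb$lower - 1e-9 &
                               truth + shift <= fb$upper + 1e-9)
  }
  expect_gte(covered / n_reps, 0.90)
})

test_that("sensitivity sweeps reproduce the directional responses", {
  s <- builtin_series("steady")
  cfg <- quiet_cfg()
  never_to_inf <- function(x) ifelse(is.na(x), Inf, x)

  sw_px <- sensitivity_sweep(s, "px", c(0.4, 0.6, 0.75, 0.9, 1), config = cfg)
  expect_true(all(diff(never_to_inf(sw_px$trigger_year)) <= 0))

  sw_w2 <- sensitivity_sweep(s, "w2", c(0.4, 0.55, 2 / 3, 0.85, 1),
                             config = cfg)
  expect_true(all(diff(never_to_inf(sw_w2$trigger_year)) <= 0))

  w1c <- log(20) / s$abundance[1]
  sw_w1 <- sensitivity_sweep(s, "w1", w1c * c(0.25, 0.5, 1, 2, 4),
                             config = cfg)
  expect_true(all(diff(never_to_inf(sw_w1$trigger_year)) >= 0))
  expect_equal(names(sw_w1),
               c("param", "value", "trigger_year", "n_failures_at_trigger",
                 "outcome"))
})
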