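test_that("a pure exponential is fit exactly, with no lag and the first window winning ties", {
  t <- seq(0, 12, by = 0.5)[1:25]
  s <- od_series(t, 0.5 * exp(0.2 * t))
  fit <- growth_fit(s)
  expect_equal(fit$mu_max, 0.2, tolerance = 1e-10)
  expect_true(is.na(fit$lag))
  expect_equal(fit$od_max, s$od600[25])
  expect_equal(fit$window_start, 0)  # all windows tie; earliest wins
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("growth parameters are recovered on a noiseless lagged curve", {
  cfg <- growth_sim_config(mu_true = 0.71, lag_true = 5.19,
                           od_max_true = 20.86, noise_sd = 0)
  fit <- growth_fit(simulate_growth_curve(cfg))
  expect_equal(fit$mu_max, 0.71, tolerance = 0.10 * 0.71)
  expect_equal(fit$lag, 5.19, tolerance = 0.10 * 5.19)
  expect_equal(fit$od_max, 20.86, tolerance = 0.02 * 20.86)
  expect_equal(fit$generation_time, log(2) / fit$mu_max)
  expect_lt(fit$lag, fit$window_start)
})

test_that("a flat series is flagged no-growth with sensible parameters", {
  s <- od_series(seq(0, 10, 0.5), rep(2, 21))
  fit <- growth_fit(s)
  expect_true(fit$no_growth)
  expect_equal(fit$od_max, 2)
  expect_true(is.na(fit$lag))
  expect_true(is.na(fit$generation_time))
  expect_error(select_timepoints(s, fit), "no growth")
})

test_that("fit is invariant to uniform OD rescaling (log-slope property)", {
  cfg <- growth_sim_config(mu_true = 0.42, lag_true = 3.38,
                           od_max_true = 23.71, noise_sd = 0.02, seed = 9L)
  s <- simulate_growth_curve(cfg)
  f1 <- growth_fit(s)
  s2 <- od_series(s$time_h, s$od600 * 7)
  f2 <- growth_fit(s2)
  expect_equal(f2$mu_max, f1$mu_max, tolerance = 1e-12)
  expect_equal(f2$lag, f1$lag, tolerance = 1e-9)
  expect_equal(f2$od_max, 7 * f1$od_max, tolerance = 1e-12)
})

test_that("window bounds are validated", {
  s <- od_series(0:5, 0.5 * exp(0.2 * (0:5)))
  expect_error(growth_fit(s, window = 2), "at least 3")
  expect_error(growth_fit(s, window = 10), "fewer points")
})

test_that("generation time is ln(2)/mu and strictly decreasing in mu", {
  expect_equal(round(generation_time(0.78), 2), 0.89)
  expect_equal(round(generation_time(0.26), 2), 2.67)
  expect_equal(generation_time(log(2)), 1)
  expect_error(generation_time(0), "positive")
  expect_error(generation_time(-1), "positive")
  mus <- seq(0.05, 1.5, by = 0.05)
  expect_true(all(diff(generation_time(mus)) < 0))
})

test_that("time points sit where interpolation first reaches the OD targets", {
  cfg <- growth_sim_config(mu_true = 0.42, lag_true = 3.38,
                           od_max_true = 23.71, noise_sd = 0,
                           sampling_interval = 0.5, duration = 40)
  s <- simulate_growth_curve(cfg)
  fit <- growth_fit(s)
  tp <- select_timepoints(s, fit)
  expect_equal(tp$timepoint, c("fifth", "half", "max"))
  expect_true(all(diff(tp$time_h) > 0))
  # brute-force crossing oracle on the dense model curve
  model <- function(t) oleagin:::od_model(cfg, t)
  for (i in 1:3) {
    oracle_t <- oracle_first_crossing(model, tp$target_od[i], 40)
    expect_equal(tp$time_h[i], oracle_t, tolerance = 0.3)
  }
  expect_equal(tp$od_at[2], fit$od_max / 2, tolerance = 0.02 * fit$od_max)
})

test_that("unreached OD targets are reported as NA with a warning", {
  cfg <- growth_sim_config(mu_true = 0.3, od_max_true = 20, noise_sd = 0,
                           duration = 40)
  full <- simulate_growth_curve(cfg)
  fit <- growth_fit(full)
  early <- od_series(full$time_h[1:30], full$od600[1:30])
  expect_warning(tp <- select_timepoints(early, fit), "never reached")
  expect_true(is.na(tp$time_h[tp$timepoint == "max"]))
})

test_that("growth_fit methods behave as a model object", {
  cfg <- growth_sim_config(mu_true = 0.5, lag_true = 2, od_max_true = 15,
                           noise_sd = 0.02, seed = 11L)
  s <- simulate_growth_curve(cfg)
  fit <- growth_fit(s)
  expect_named(coef(fit), c("mu_max", "lag", "od_max", "generation_time"))
  expect_length(fitted(fit), nrow(s))
  expect_equal(residuals(fit), s$od600 - fitted(fit))
  expect_output(print(fit), "mu_max")
  expect_output(print(summary(fit)), "observations")
  sims <- simulate(fit, nsim = 2, seed = 4L)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "od_series")
  # predictions saturate at the fitted OD max
  pr <- predict(fit, data.frame(time_h = c(0, 100)))
  expect_equal(pr[2], fit$od_max)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
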