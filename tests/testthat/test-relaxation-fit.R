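test_that("model_eval satisfies its boundary and half-decay identities", {
  expect_equal(model_eval(1, 0.1, 1, 0.5, 0), 1.5)
  expect_equal(model_eval(1, 0.1, 1, 0.5, 1e6), 0.5, tolerance = 1e-12)
  expect_equal(model_eval(1, 0.1, 1, 0.5, log(2) / 0.1), 1.0)
  expect_equal(model_eval(2, 0.3, 0.7, 0.1, 0), 2.1)
  expect_error(model_eval(1, 0.1, 1, 0.5, -1), "domain")
})

test_that("initial_guess lands within 20% of truth on clean curves", {
  tm <- seq(0, 59, by = 1 / 60)
  for (tissue in tissue_levels()) {
    pars <- mean_params(tissue, "relative")
    a <- pars$p0 * (1 - pars$rcp_loss) - pars$plateau
    b <- -log(1 - pars$decline_per_min)
    y <- model_eval(a, b, 1, pars$plateau, tm)
    g <- initial_guess(tm, y)
    expect_false(g$flat)
    expect_lt(abs(g$a0 - a) / a, 0.2)
    expect_lt(abs(g$b0 - b) / b, 0.2)
    expect_lt(abs(g$d0 - pars$plateau) / pars$plateau, 0.2)
  }
})

test_that("initial_guess degrades gracefully on flat or two-phase input", {
  tm <- seq(0, 59, by = 0.5)
  g <- initial_guess(tm, rep(1.0, length(tm)))
  expect_true(g$flat)
  expect_equal(g$b0, 1e-3)
  # full window including the rapid phase: d0 still finite and >= 0
  t <- seq(0, 59, by = 0.5)
  y <- 1.0 + 0.7 * exp(-t * 60 / 10) + 0.6 * exp(-0.1 * t)
  g2 <- initial_guess(t, y)
  expect_true(is.finite(g2$d0) && g2$d0 >= 0)
  expect_error(initial_guess(1:5, 1:5), "10 points")
})

test_that("noiseless curves are recovered to high relative accuracy", {
  # trace generated directly from (a, b, c, d) with no noise/quantization
  truth <- list(a = 0.7, b = 0.12, c = 1, d = 0.9)
  t <- seq(60, 3599, by = 1)
  y <- model_eval(truth$a, truth$b, 1, truth$d, (t - 60) / 60)
  tr <- make_trace(c(0.5, t), c(truth$a + truth$d, y), hz = 1)
  f <- fit_relaxation(tr, window = c(60, NA))
  expect_true(f$converged)
  expect_lt(abs(f$a - truth$a) / truth$a, 1e-4)
  expect_lt(abs(f$b - truth$b) / truth$b, 1e-4)
  expect_lt(abs(f$d - truth$d) / truth$d, 1e-4)
  expect_gt(f$r_fit, 1 - 1e-9)
  # freeing c on a c = 1 truth still recovers the pure exponential
  fc <- fit_relaxation(tr, window = c(60, NA), free_c = TRUE)
  expect_lt(abs(fc$c - 1), 1e-3)
})

test_that("r_fit is 1 within 1e-9 on unquantized generator output", {
  for (tissue in c("liver", "stomach")) {
    tr <- synthesize_trace(mean_params(tissue), sens_pure(hz = 1))
    f <- fit_relaxation(tr)
    expect_true(f$converged)
    expect_gt(f$r_fit, 1 - 1e-9)
  }
})

test_that("decline_per_minute maps b to the printed per-minute percentages", {
  mkfit <- function(a, b, c, d, wmin = 59)
    structure(list(a = a, b = b, c = c, d = d, window_min = wmin,
                   converged = TRUE), class = "relaxation_fit")
  expect_equal(decline_per_minute(mkfit(1, -log(0.92), 1, 0.5)), 8.0)
  expect_equal(decline_per_minute(mkfit(1, -log(0.85), 1, 0.5)), 15.0)
  expect_equal(decline_per_minute(mkfit(1, 1e-12, 1, 0.5)), 0, tolerance = 1e-9)
  # c != 1: geometric-mean decline equals the c = 1 value when c = 1 anyway
  expect_equal(decline_per_minute(mkfit(1, -log(0.9), 0.999999, 0.5)),
               100 * (1 - 0.9), tolerance = 1e-3)
  expect_error(decline_per_minute(mkfit(-0.1, 0.1, 1, 0.5)), "undefined")
})

test_that("model-implied and measured half-tension times agree", {
  # closed form: d = 1.04, a = 0.676, b = -log(0.92), p0 = 2.6 -> ~12.5 min
  f <- structure(list(a = 0.676, b = -log(0.92), c = 1, d = 1.04,
                      window = c(60, 3600), window_min = 59, converged = TRUE),
                 class = "relaxation_fit")
  ht <- half_time_from_fit(f, 2.6)
  expect_equal(ht$time_min, 1 + log(0.676 / 0.26) / -log(0.92),
               tolerance = 1e-9)
  expect_false(ht$censored)

  # skin-like: d/p0 = 60% -> censored
  fs <- structure(list(a = 0.5, b = 0.1, c = 1, d = 1.32,
                       window = c(60, 3600), window_min = 59, converged = TRUE),
                  class = "relaxation_fit")
  expect_true(half_time_from_fit(fs, 2.2)$censored)

  # threshold equals the curve start -> 1-minute boundary flag
  fb <- structure(list(a = 1, b = log(2), c = 1, d = 0,
                       window = c(60, 3600), window_min = 59, converged = TRUE),
                  class = "relaxation_fit")
  hb <- half_time_from_fit(fb, 2)
  expect_true(hb$boundary)
  expect_equal(hb$time_min, 1)

  # on noiseless generator output both half-time routes agree to ~1 sample
  for (tissue in c("liver", "muscle")) {
    tr <- synthesize_trace(mean_params(tissue), sens_noiseless(hz = 1))
    m <- segment_phases(tr)
    f2 <- fit_relaxation(tr)
    h2 <- half_time_from_fit(f2, m$p0)
    expect_identical(h2$censored, m$half_time_censored)
    expect_lt(abs(h2$time_min - m$half_time_min), 1.5 / 60)
  }
  # free-c bisection path agrees with the closed form on a c = 1 truth
  ffree <- structure(list(a = 0.676, b = -log(0.92), c = 1.0000001, d = 1.04,
                          window = c(60, 3600), window_min = 59,
                          converged = TRUE), class = "relaxation_fit")
  expect_equal(half_time_from_fit(ffree, 2.6)$time_min, ht$time_min,
               tolerance = 1e-4)
})

test_that("the fit is equivariant under uniform force rescaling", {
  set.seed(13)
  pars <- mean_params("small_intestine")
  sen <- sensor_config(sampling_hz = 2, quantization_step_n = 0)
  tr <- synthesize_trace(pars, sen)
  f1 <- fit_relaxation(tr)
  k <- 3.7
  tr2 <- tr; tr2$forces <- k * tr$forces
  f2 <- fit_relaxation(tr2)
  expect_equal(f2$a, k * f1$a, tolerance = 1e-6)
  expect_equal(f2$d, k * f1$d, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  expect_equal(f2$r_fit, f1$r_fit, tolerance = 1e-9)
})

test_that("degenerate windows and inputs raise validation errors", {
  t <- seq(0, by = 1, length.out = 3600)
  tr <- make_trace(t, 1 + exp(-t / 500))
  expect_error(fit_relaxation(tr, window = c(3595, NA)), "10 points")
  expect_error(fit_relaxation(tr, window = c(4000, 5000)), "window")
})
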