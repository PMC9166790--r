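test_that("eta16 calibration matches the bisection oracle and the 16-pulse anchor", {
  p <- device_params()
  expect_equal(p$eta16, oracle_eta16(), tolerance = 1e-10)

  s <- device_state()
  pulse <- pulse_spec(4.5, 100e-6, "set")
  for (i in 1:16) s <- apply_set_pulse(s, pulse, p)
  expect_equal(conductance(s, p), 1200e-9, tolerance = 1e-12)

  # zero pulses: baseline
  expect_equal(conductance(device_state(), p), 55e-9)
})

test_that("set pulses are saturating, monotone and bounded", {
  p <- device_params()
  pulse <- pulse_spec(4.5, 100e-6, "set")
  s <- device_state(w = 0)
  for (i in 1:2000) {
    s2 <- apply_set_pulse(s, pulse, p)
    expect_gt(s2$w, s$w)
    expect_lte(s2$w, 1)
    s <- s2
  }
  g <- conductance(s, p)
  expect_gte(g, p$g_off); expect_lte(g, p$g_on)

  # width scaling: a 10 us pulse has the first-order fraction of the gain
  eta10 <- pulse_gain(pulse_spec(4.5, 10e-6, "set"), p)
  expect_equal(eta10, 1 - (1 - p$eta16)^(0.1), tolerance = 1e-12)
  # amplitude below the set minimum is rejected without an explicit gain
  expect_error(pulse_gain(pulse_spec(2.5, 100e-6, "set"), p), "minimum set amplitude")
  s3 <- apply_set_pulse(device_state(), pulse_spec(2.5, 100e-6, "set"), p, gain = 0.1)
  expect_equal(s3$w, 0.1)
})

test_that("decay follows the exponential law and composes as a semigroup", {
  p <- device_params()
  s <- device_state(w = 1)
  expect_equal(decay(s, 0, p)$w, 1)
  expect_equal(decay(s, 40e-3, p)$w, exp(-1), tolerance = 1e-12)
  expect_error(decay(s, -1e-3, p), "non-negative")

  set.seed(42)
  for (i in 1:20) {
    w0 <- runif(1); dt <- runif(1, 0, 0.2); duty <- runif(1, 0.05, 0.95)
    one <- decay(device_state(w = w0), dt, p, duty = duty)
    two <- decay(decay(device_state(w = w0), dt / 2, p, duty = duty),
                 dt / 2, p, duty = duty)
    expect_equal(two$w, one$w, tolerance = 1e-12)
    expect_equal(one$t, dt)
  }
})

test_that("duty -> tau map hits the printed anchors and is monotone", {
  p <- device_params()
  expect_equal(tau_duty(p, 0.15), 15e-3)
  expect_equal(tau_duty(p, 0.85), 40e-3)
  expect_equal(tau_duty(p, NULL), 40e-3)
  duties <- c(0.02, 0.05, 0.10, 0.15, 0.20, 0.5, 0.85)
  taus <- vapply(duties, function(d) tau_duty(p, d), numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_true(all(taus > 0))
  expect_equal(tau_duty(p, 0.95), 40e-3) # clamped above
})

test_that("reads are rectified, linear and non-perturbing", {
  p <- device_params()
  s <- device_state(w = 0)
  expect_equal(read_current(s, 1.5, p), 55e-9 * 1.5, tolerance = 1e-12)
  expect_error(read_current(s, 0, p), "non-zero")
  set.seed(1)
  for (w in runif(5)) {
    st <- device_state(w = w)
    ip <- read_current(st, 1.5, p)
    im <- read_current(st, -1.5, p)
    expect_equal(ip / abs(im), 1e4, tolerance = 1e-12)
    expect_equal(read_current(st, 3.0, p), 2 * ip, tolerance = 1e-12)
    expect_equal(st$w, w) # unchanged
  }
})

test_that("fit_time_constant inverts the decay law", {
  p <- device_params()
  g0 <- 1200e-9
  ts <- seq(0, 0.2, by = 2e-3)
  for (tau in c(40e-3, 15e-3)) {
    g <- p$g_off + (g0 - p$g_off) * exp(-ts / tau)
    expect_equal(fit_time_constant(ts, g, p), tau, tolerance = 1e-9)
  }
  # 1% multiplicative noise, 200 samples: within 5% of truth
  set.seed(7)
  ts2 <- seq(0, 0.2, length.out = 200)
  g <- p$g_off + (g0 - p$g_off) * exp(-ts2 / 40e-3) * exp(rnorm(200, 0, 0.01))
  expect_equal(fit_time_constant(ts2, g, p), 40e-3, tolerance = 0.05)
  expect_error(fit_time_constant(ts, rep(p$g_off, length(ts)), p), "baseline")
})

test_that("activation energy estimation inverts the Arrhenius law", {
  p <- device_params()
  temps <- c(323, 353, 383, 423)
  taus <- vapply(temps, function(T) tau_effective(p, NULL, T), numeric(1))
  expect_equal(estimate_activation_energy(temps, taus), 0.21, tolerance = 1e-9)
  # tau decreases with temperature
  expect_true(all(diff(taus) < 0))
  # constant tau -> zero activation energy
  expect_equal(estimate_activation_energy(temps, rep(40e-3, 4)), 0, tolerance = 1e-12)
  # two points match the analytic slope
  e2 <- estimate_activation_energy(temps[1:2], taus[1:2])
  slope <- (log(taus[2]) - log(taus[1])) / (1 / temps[2] - 1 / temps[1])
  expect_equal(e2, slope * 8.617333262e-5, tolerance = 1e-12)
  expect_error(estimate_activation_energy(c(300, 300), c(1, 2)), "distinct")
})

test_that("device sampling reproduces the stated spatial variation", {
  p <- device_params()
  expect_identical(sample_device(device_params(cv_spatial = 0), 1),
                   device_params(cv_spatial = 0))
  expect_equal(sample_device(p, 99), sample_device(p, 99))
  taus <- vapply(1:10000, function(i) sample_device(p, i)$tau_ref, numeric(1))
  expect_equal(sd(taus) / mean(taus), 0.0387, tolerance = 0.05)
  expect_equal(mean(taus), p$tau_ref, tolerance = 0.01)
})
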