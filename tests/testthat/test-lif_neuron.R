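test_that("simulate matches the closed-form RC recurrence when not firing", {
  circ <- neuron_circuit(47e3, v_th = 10) # unreachable threshold
  tr <- spike_train(amplitude = 4, width = 200e-6, interval = 50e-6, count = 6)
  expect_warning(trace <- simulate_neuron(circ, tr, dt = 1e-6), "never fire")
  # compare at a set of probe times against the independent oracle
  probes <- c(5e-5, 1.5e-4, 2.2e-4, 6e-4, 1.1e-3, 1.4e-3)
  for (tp in probes) {
    i <- which.min(abs(trace$times - tp))
    expect_equal(trace$v_c[i],
                 oracle_rc_voltage(trace$times[i], 47e3),
                 tolerance = 1e-6)
  }
  expect_equal(nrow(trace$fires), 0)
  # v_c bounded by [0, amplitude]
  expect_true(all(trace$v_c >= 0 & trace$v_c <= 4))
})

test_that("printed spike counts are reproduced with the default threshold", {
  tr <- spike_train(count = 10)
  expect_identical(spikes_to_fire(neuron_circuit(47e3), tr), 3L)
  expect_identical(spikes_to_fire(neuron_circuit(94e3), tr), 6L)
  expect_identical(spikes_to_fire(neuron_circuit(23.5e3), tr), 2L)
  expect_identical(spikes_to_fire(neuron_circuit(47e3),
                                  spike_train_hz(1600, count = 50), 50),
                   NA_integer_)
  expect_lte(spikes_to_fire(neuron_circuit(47e3), spike_train_hz(3200)), 3L)
  # the event-driven simulator agrees with the peak recurrence
  trace <- simulate_neuron(neuron_circuit(47e3), tr, dt = 1e-6)
  expect_identical(trace$fires$pulse[1], 3L)
  # zero-amplitude train: flat at zero
  tr0 <- spike_train(amplitude = 0, count = 5)
  expect_warning(t0 <- simulate_neuron(neuron_circuit(47e3), tr0), "never fire")
  expect_true(all(t0$v_c == 0))
})

test_that("threshold calibration reproduces the oracle window", {
  win <- calibrate_threshold(reference_constraints())
  # frozen from the independent recurrence oracle
  p47 <- oracle_pulse_peaks(47e3); p94 <- oracle_pulse_peaks(94e3)
  p23 <- oracle_pulse_peaks(23.5e3)
  p16 <- oracle_pulse_peaks(47e3, interval = 1 / 1600 - 200e-6)
  p32 <- oracle_pulse_peaks(47e3, interval = 1 / 3200 - 200e-6)
  lo <- max(p47[2], p94[5], p16)
  hi <- min(p47[3], p94[6], p23[2], p32[3])
  expect_close(win["lo"], lo, tol = 1e-9)
  expect_close(win["hi"], hi, tol = 1e-9)
  expect_close(win["lo"], 2.4132368, tol = 1e-6)
  expect_close(win["hi"], 2.4653755, tol = 1e-6)
  # without the 3200 Hz bound the window widens to the resistor-sweep one
  win4 <- calibrate_threshold(reference_constraints()[-4])
  expect_close(win4["hi"], min(p47[3], p94[6], p23[2]), tol = 1e-9)
  expect_close(win4["hi"], 2.6157603, tol = 1e-6)
})

test_that("calibration handles trivial and contradictory constraint sets", {
  circ <- neuron_circuit(47e3, v_th = 1)
  tr <- spike_train(count = 10)
  w1 <- calibrate_threshold(list(list(circuit = circ, train = tr, fires_on = 1L)))
  expect_equal(unname(w1["lo"]), 0)
  expect_close(w1["hi"], oracle_pulse_peaks(47e3)[1], tol = 1e-9)
  expect_error(calibrate_threshold(list(
    list(circuit = circ, train = tr, fires_on = 3L),
    list(circuit = circ, train = tr, fires_on = 2L)
  )), "violated")
})

test_that("spikes_to_fire is monotone in resistance, amplitude and frequency", {
  fires <- function(r, amp = 4, interval = 50e-6)
    spikes_to_fire(neuron_circuit(r),
                   spike_train(amplitude = amp, interval = interval, count = 60), 60)
  rs <- c(10e3, 23.5e3, 47e3, 70e3, 94e3, 150e3)
  fr <- vapply(rs, fires, integer(1))
  expect_true(all(diff(fr) >= 0, na.rm = TRUE))
  amps <- c(3.2, 3.6, 4, 4.4)
  fa <- vapply(amps, function(a) fires(47e3, amp = a), integer(1))
  expect_true(all(diff(fa) <= 0, na.rm = TRUE))
  ints <- c(20e-6, 50e-6, 150e-6, 300e-6)
  fi <- vapply(ints, function(i) fires(47e3, interval = i), integer(1))
  expect_true(all(diff(fi) >= 0, na.rm = TRUE))
})

test_that("the trajectory is invariant under R*C-preserving rescaling", {
  tr <- spike_train(count = 8)
  a <- neuron_circuit(47e3, c = 10e-9, v_th = 2.44, r_off = 1e8)
  b <- neuron_circuit(94e3, c = 5e-9, v_th = 2.44, r_off = 2e8)
  expect_identical(spikes_to_fire(a, tr), spikes_to_fire(b, tr))
  expect_equal(pulse_peaks(a, tr), pulse_peaks(b, tr), tolerance = 1e-12)
})

test_that("with no leak and no gaps the peak approaches the closed-form limit", {
  n <- 5
  circ <- neuron_circuit(47e3, v_th = 100, r_off = 1e15)
  tr <- spike_train(amplitude = 4, width = 200e-6, interval = 1e-12, count = n)
  peak <- pulse_peaks(circ, tr)[n]
  expect_equal(peak, 4 * (1 - exp(-n * 200e-6 / (47e3 * 10e-9))),
               tolerance = 1e-6)
})
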