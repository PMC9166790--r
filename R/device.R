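# Phenomenological model of one gradual-TiOx volatile memristor.
#
# The device is described by a normalized internal state w in [0, 1] with
# conductance G = g_off + w * (g_on - g_off). Set pulses potentiate w with a
# saturating geometric update; between pulses w relaxes exponentially toward
# zero (the short-term / volatile memory effect). Reads are Ohmic, strongly
# rectified, and non-perturbing.

#' Boltzmann constant in eV/K
#' @keywords internal
.k_B_eV <- 8.617333262e-5

#' Device parameters for a gradual-TiOx volatile memristor
#'
#' Constructs the parameter set of the phenomenological device model. Inputs
#' use the bench units conventional for these devices (nS, ms, eV, K);
#' internally everything is stored in SI units (S, s).
#'
#' The per-pulse potentiation gain `eta16` is not supplied directly: it is
#' calibrated from the anchor that 16 reference set pulses (4.5 V, 100 us)
#' drive the conductance from `g_off_ns` to `g16_ns`, i.e. it solves
#' `g_off + (1 - (1 - eta)^16) * (g_on - g_off) = g16` in closed form.
#'
#' @param g_off_ns Baseline (off-state) conductance in nS. Default 55.
#' @param g_on_ns Saturation conductance in nS. Default 1.5e5 (about 2700x
#'   the baseline at read).
#' @param tau_ref_ms Self-decay time constant in ms at reference temperature
#'   with no duty-cycled driving. Default 40.
#' @param ea_ev Activation energy of the decay process in eV. Default 0.21.
#' @param t_ref_k Reference temperature in K. Default 300.
#' @param rectification_ratio Forward/reverse read-current ratio. Default 1e4.
#' @param g16_ns Conductance anchor after 16 reference set pulses, in nS.
#'   Default 1200.
#' @param v_set_min Minimum set amplitude in V below which a pulse does not
#'   potentiate. Default 3.0.
#' @param set_ref_amplitude,set_ref_width Amplitude (V) and width (s) of the
#'   reference set pulse used for the `eta16` calibration.
#' @param cv_spatial Device-to-device coefficient of variation (sigma/mu)
#'   applied by [sample_device()]. Default 0.0387.
#' @param cv_cycle Cycle-to-cycle coefficient of variation. Default 0.0139.
#' @return An object of class `device_params`.
#' @examples
#' p <- device_params()
#' p$eta16 # per-pulse gain implied by the 16-pulse anchor
#' @export
device_params <- function(g_off_ns = 55, g_on_ns = 1.5e5, tau_ref_ms = 40,
                          ea_ev = 0.21, t_ref_k = 300,
                          rectification_ratio = 1e4, g16_ns = 1200,
                          v_set_min = 3.0, set_ref_amplitude = 4.5,
                          set_ref_width = 100e-6,
                          cv_spatial = 0.0387, cv_cycle = 0.0139) {
  stopifnot(g_off_ns > 0, g_on_ns > g_off_ns, tau_ref_ms > 0, ea_ev >= 0,
            rectification_ratio >= 1, cv_spatial >= 0, cv_cycle >= 0,
            g16_ns > g_off_ns, g16_ns < g_on_ns, t_ref_k > 0,
            set_ref_width > 0, set_ref_amplitude > v_set_min)
  eta16 <- 1 - ((g_on_ns - g16_ns) / (g_on_ns - g_off_ns))^(1 / 16)
  structure(list(
    g_off = g_off_ns * 1e-9, g_on = g_on_ns * 1e-9,
    tau_ref = tau_ref_ms * 1e-3, ea = ea_ev, t_ref = t_ref_k,
    rectification_ratio = rectification_ratio, eta16 = eta16,
    v_set_min = v_set_min, set_ref_amplitude = set_ref_amplitude,
    set_ref_width = set_ref_width,
    cv_spatial = cv_spatial, cv_cycle = cv_cycle
  ), class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat("Gradual-TiOx volatile memristor parameters\n")
  cat(sprintf("  G_off %.4g nS, G_on %.4g nS, tau_ref %.4g ms (E_A %.3g eV at %g K)\n",
              x$g_off * 1e9, x$g_on * 1e9, x$tau_ref * 1e3, x$ea, x$t_ref))
  cat(sprintf("  eta16 %.6g (anchored on 16 x %.2g V / %.3g us set pulses)\n",
              x$eta16, x$set_ref_amplitude, x$set_ref_width * 1e6))
  cat(sprintf("  rectification %g, CV spatial %.3g%% / cycle %.3g%%\n",
              x$rectification_ratio, 100 * x$cv_spatial, 100 * x$cv_cycle))
  invisible(x)
}

#' Device state
#'
#' @param w Internal state in `[0, 1]`; conductance is
#'   `g_off + w * (g_on - g_off)`.
#' @param t Elapsed time (s).
#' @param temperature Device temperature (K).
#' @return Object of class `device_state`.
#' @export
device_state <- function(w = 0, t = 0, temperature = 300) {
  stopifnot(w >= 0, w <= 1, t >= 0, temperature > 0)
  structure(list(w = w, t = t, temperature = temperature),
            class = "device_state")
}

#' Conductance of a device state
#'
#' @param state A [device_state()].
#' @param params A [device_params()].
#' @return Conductance in siemens.
#' @export
conductance <- function(state, params) {
  params$g_off + state$w * (params$g_on - params$g_off)
}

#' Pulse specification
#'
#' @param amplitude Pulse amplitude (V), non-negative.
#' @param width Pulse width (s), positive.
#' @param polarity One of "set", "reset", "read".
#' @return Object of class `pulse_spec`.
#' @export
pulse_spec <- function(amplitude, width, polarity = c("set", "reset", "read")) {
  polarity <- match.arg(polarity)
  stopifnot(width > 0, amplitude >= 0)
  structure(list(amplitude = amplitude, width = width, polarity = polarity),
            class = "pulse_spec")
}

#' Per-pulse potentiation gain for a set pulse
#'
#' The gain is anchored at the reference protocol (4.5 V, 100 us) and scaled
#' by a first-order width rule, `eta(W) = 1 - (1 - eta_ref)^(W/W_ref)`, and a
#' linear amplitude factor `(V - v_set_min) / (V_ref - v_set_min)` entering
#' the same exponent. Pulses at or below `v_set_min` do not potentiate and
#' are rejected unless an explicit gain is supplied to [apply_set_pulse()].
#'
#' @param pulse A [pulse_spec()] with polarity "set".
#' @param params A [device_params()].
#' @return Gain eta in (0, 1).
#' @export
pulse_gain <- function(pulse, params) {
  if (!identical(pulse$polarity, "set"))
    stop("pulse_gain() is defined for set pulses, got polarity '",
         pulse$polarity, "'")
  amp_factor <- (pulse$amplitude - params$v_set_min) /
    (params$set_ref_amplitude - params$v_set_min)
  if (amp_factor <= 0)
    stop(sprintf(
      "set pulse (%.3g V, %.3g us) is below the minimum set amplitude %.3g V; supply an explicit gain",
      pulse$amplitude, pulse$width * 1e6, params$v_set_min))
  expo <- amp_factor * pulse$width / params$set_ref_width
  1 - (1 - params$eta16)^expo
}

#' Apply one set pulse to a device
#'
#' Saturating geometric update `w <- w + eta * (1 - w)`; time advances by the
#' pulse width. The conductance strictly increases unless `w == 1`.
#'
#' @param state A [device_state()].
#' @param pulse A [pulse_spec()] with polarity "set".
#' @param params A [device_params()].
#' @param gain Optional explicit gain overriding the calibrated protocol
#'   scaling (required for amplitudes at or below `v_set_min`).
#' @return The updated `device_state`.
#' @export
apply_set_pulse <- function(state, pulse, params, gain = NULL) {
  eta <- if (is.null(gain)) pulse_gain(pulse, params) else gain
  stopifnot(eta > 0, eta < 1)
  state$w <- state$w + eta * (1 - state$w)
  state$t <- state$t + pulse$width
  state
}

#' Effective decay time constant
#'
#' Combines the duty-cycle map with the Arrhenius temperature law:
#' `tau_eff = tau(duty) * exp((E_A / k_B) * (1/T - 1/T_ref))`.
#'
#' The duty map is linear through the anchors tau(0.15) = 15 ms and
#' tau(0.85) = 40 ms (scaled if `tau_ref` differs from 40 ms), extrapolated
#' linearly below duty 0.15 and clamped above 0.85, so that smaller duty
#' cycles always decay strictly faster. `duty = NULL` means no duty-cycled
#' driving and returns `tau_ref` (temperature-adjusted).
#'
#' @param params A [device_params()].
#' @param duty Write-slot duty cycle in (0, 1), or `NULL`.
#' @param temperature Temperature in K; default `params$t_ref`.
#' @return Time constant in seconds.
#' @export
tau_effective <- function(params, duty = NULL, temperature = NULL) {
  if (is.null(temperature)) temperature <- params$t_ref
  tau <- tau_duty(params, duty)
  tau * exp((params$ea / .k_B_eV) * (1 / temperature - 1 / params$t_ref))
}

#' @rdname tau_effective
#' @export
tau_duty <- function(params, duty = NULL) {
  if (is.null(duty)) return(params$tau_ref)
  stopifnot(duty > 0, duty < 1)
  d <- min(duty, 0.85)
  tau_ms <- 15 + (d - 0.15) * (40 - 15) / (0.85 - 0.15)
  tau_ms * 1e-3 * (params$tau_ref / 40e-3)
}

#' Self-decay of the device state
#'
#' `w <- w * exp(-dt / tau_eff)`. Composes as a semigroup:
#' `decay(dt1)` then `decay(dt2)` equals `decay(dt1 + dt2)`.
#'
#' @param state A [device_state()].
#' @param dt Elapsed time (s), non-negative.
#' @param params A [device_params()].
#' @param duty Duty cycle passed to [tau_effective()], or `NULL`.
#' @param temperature Temperature (K) overriding the state's; optional.
#' @return The updated `device_state`.
#' @export
decay <- function(state, dt, params, duty = NULL, temperature = NULL) {
  if (dt < 0) stop("dt must be non-negative, got ", dt)
  temp <- if (is.null(temperature)) state$temperature else temperature
  tau <- tau_effective(params, duty, temp)
  state$w <- state$w * exp(-dt / tau)
  state$t <- state$t + dt
  state
}

#' Rectified read current
#'
#' Ohmic for positive read voltages; suppressed by the rectification ratio
#' for negative voltages. Reading does not perturb the state.
#'
#' @param state A [device_state()].
#' @param v_read Read voltage (V), non-zero.
#' @param params A [device_params()].
#' @return Current in amperes.
#' @export
read_current <- function(state, v_read, params) {
  if (v_read == 0) stop("v_read must be non-zero")
  g <- conductance(state, params)
  if (v_read > 0) g * v_read else g * v_read / params$rectification_ratio
}

#' Fit the decay time constant from a conductance trace
#'
#' Least-squares fit of `log(G - g_off)` against time.
#'
#' @param time_s Sample times (s).
#' @param conductance_S Conductances (S), above baseline.
#' @param params A [device_params()] supplying the baseline `g_off`.
#' @return Fitted time constant in seconds.
#' @export
fit_time_constant <- function(time_s, conductance_S, params = device_params()) {
  stopifnot(length(time_s) == length(conductance_S))
  keep <- conductance_S > params$g_off
  if (!any(keep)) stop("all samples are at the baseline g_off; nothing to fit")
  if (sum(keep) < 3) stop("need at least 3 samples above baseline")
  y <- log(conductance_S[keep] - params$g_off)
  fit <- stats::lm.fit(cbind(1, time_s[keep]), y)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    stop("trace does not decay; fitted slope is ", slope)
  unname(-1 / slope)
}

#' Estimate the activation energy from time constants across temperatures
#'
#' Arrhenius analysis: the slope of `ln(tau)` against `1/T`, times the
#' Boltzmann constant, in eV.
#'
#' @param temperature_K Temperatures (K), at least two distinct values.
#' @param tau_s Time constants (s) measured at those temperatures.
#' @return Activation energy in eV.
#' @export
estimate_activation_energy <- function(temperature_K, tau_s) {
  stopifnot(length(temperature_K) == length(tau_s), all(tau_s > 0))
  if (length(unique(temperature_K)) < 2)
    stop("need at least two distinct temperatures")
  fit <- stats::lm.fit(cbind(1, 1 / temperature_K), log(tau_s))
  unname(fit$coefficients[2] * .k_B_eV)
}

#' Sample a device instance with spatial variation
#'
#' Returns a copy of `params` whose `g_on`, `eta16`, and `tau_ref` are each
#' multiplied by independent lognormal factors with mean 1 and coefficient of
#' variation `cv_spatial`. Deterministic given the seed.
#'
#' @param params A [device_params()].
#' @param rng_seed Integer seed.
#' @return A new `device_params` object.
#' @export
sample_device <- function(params, rng_seed) {
  cv <- params$cv_spatial
  if (cv == 0) return(params)
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  f <- stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  params$g_on <- params$g_on * f[1]
  params$eta16 <- min(params$eta16 * f[2], 1 - 1e-12)
  params$tau_ref <- params$tau_ref * f[3]
  params
}
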