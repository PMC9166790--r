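# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Closed-form RC pulse-peak recurrence for the neuron circuit: charging
# toward A_inf during a pulse, grounded-input discharge between pulses.
oracle_pulse_peaks <- function(r_series, amplitude = 4, width = 200e-6,
                               interval = 50e-6, c = 10e-9, r_off = 1e8,
                               n = 60) {
  tau <- c * r_series * r_off / (r_series + r_off)
  a_inf <- amplitude * r_off / (r_series + r_off)
  ew <- exp(-width / tau); ei <- exp(-interval / tau)
  v <- 0
  out <- numeric(n)
  for (k in seq_len(n)) {
    v <- a_inf + (v - a_inf) * ew
    out[k] <- v
    v <- v * ei
  }
  out
}

# Membrane voltage at an arbitrary time for a no-fire periodic train,
# evaluated segment by segment (independent of simulate_neuron()).
oracle_rc_voltage <- function(t, r_series, amplitude = 4, width = 200e-6,
                              interval = 50e-6, c = 10e-9, r_off = 1e8) {
  tau <- c * r_series * r_off / (r_series + r_off)
  a_inf <- amplitude * r_off / (r_series + r_off)
  period <- width + interval
  v <- 0; t0 <- 0
  repeat {
    if (t <= t0 + width + 1e-15)
      return(a_inf + (v - a_inf) * exp(-(t - t0) / tau))
    v <- a_inf + (v - a_inf) * exp(-width / tau)
    t0 <- t0 + width
    if (t <= t0 + interval + 1e-15)
      return(v * exp(-(t - t0) / tau))
    v <- v * exp(-interval / tau)
    t0 <- t0 + interval
  }
}

# Per-pulse gain from the 16-pulse anchor via bisection on the closed form.
oracle_eta16 <- function(g_off = 55e-9, g_on = 1.5e-4, g16 = 1200e-9) {
  f <- function(eta) g_off + (1 - (1 - eta)^16) * (g_on - g_off) - g16
  stats::uniroot(f, c(1e-12, 0.5), tol = 1e-15)$root
}

# Direct Henderson-Hasselbalch sums (Bjellqvist table, pH 7), written out
# term by term for the fixture peptides.
oracle_charge_magainin2 <- function() {
  pos <- function(pka, ph = 7) 1 / (1 + 10^(ph - pka))
  neg <- function(pka, ph = 7) 1 / (1 + 10^(pka - ph))
  # GIGKFLHSAKKFGKAFVGEIMNS: 4x K, 1x H, 1x E, plus termini
  pos(7.5) - neg(3.55) + 4 * pos(10) + pos(5.98) - neg(4.45)
}

oracle_charge_gg <- function() {
  pos <- function(pka, ph = 7) 1 / (1 + 10^(ph - pka))
  neg <- function(pka, ph = 7) 1 / (1 + 10^(pka - ph))
  pos(7.5) - neg(3.55)
}

# Linear-regime recency-weighted score of a symbol sequence: the relative
# final state of each symbol's cell is sum over its occurrences of
# r^(n - k), r the per-step decay factor. Used as the ordering oracle for
# the symbol-sequence protocol.
oracle_recency_scores <- function(symbols_seq, r) {
  n <- length(symbols_seq)
  syms <- sort(unique(symbols_seq))
  vapply(syms, function(s) {
    ks <- which(symbols_seq == s)
    sum(r^(n - ks))
  }, numeric(1))
}

# Average molecular weights computed by an independent implementation
# (biopython ProteinAnalysis.molecular_weight), frozen.
oracle_mw <- c(G = 75.0666, GG = 132.1179,
               GIGKFLHSAKKFGKAFVGEIMNS = 2466.8972, KAIST = 518.6043)

expect_close <- function(x, y, tol = 1e-8) expect_equal(unname(x), unname(y), tolerance = tol)
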