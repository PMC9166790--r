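---
title: "Methods: modeling a volatile-memristor reservoir for peptide generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling a volatile-memristor reservoir for peptide generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volamp)
```

## The system being simulated

`volamp` simulates a physical reservoir computer built from gradual
titanium-oxide *volatile* memristors. Each device stores its state as a
conductance that rises under voltage pulses and relaxes spontaneously back to
baseline with a time constant of tens of milliseconds. That spontaneous
forgetting is the computational resource: the conductance of a pulsed device
is a leaky integral of its recent input history, so a crossbar of such
devices maps a symbol sequence into an analog state vector that encodes
recency and frequency information. Only a small softmax network (the
*readout*) is then trained, by next-symbol cross-entropy, to predict the next
amino acid of antimicrobial-peptide (AMP) sequences; sampling from the
trained readout autoregressively generates new peptide candidates.

The package covers the full stack — device, neuron circuit, crossbar
protocols, reservoir, readout, generator, peptide evaluation, and a
synthetic training corpus — so every stage is testable offline.

## Device model

The device state is a normalized scalar $w \in [0,1]$ with conductance
$G = G_\mathrm{off} + w\,(G_\mathrm{on} - G_\mathrm{off})$,
$G_\mathrm{off} = 55$ nS, $G_\mathrm{on} = 150\ \mu$S (about $2700\times$ the
baseline). Three laws govern it:

* **Potentiation.** A set pulse applies a saturating geometric update
  $w \leftarrow w + \eta\,(1-w)$. The reference devices show saturating
  analog potentiation but no closed-form law is established, so the simplest
  law with the right fixed point was chosen. The gain $\eta$ is calibrated
  from a single anchor: sixteen reference pulses (4.5 V, 100 µs) move a
  fresh device to 1200 nS, giving $\eta_{16} \approx 4.79\times10^{-4}$ in
  closed form. Other pulse shapes scale $\eta$ first-order in width,
  $\eta(W) = 1-(1-\eta_{16})^{W/W_\mathrm{ref}}$, and linearly in amplitude
  above a 3 V set minimum. Because $\eta$ is calibrated on a back-to-back
  pulse train, it is an *effective* gain that absorbs within-train decay;
  the 16-pulse anchor is therefore reproduced exactly without inserting
  decay between calibration pulses.
* **Self-decay.** $w \leftarrow w\,e^{-\Delta t/\tau}$ with
  $\tau_\mathrm{ref} = 40$ ms at 300 K. Temperature enters through an
  Arrhenius factor with activation energy $E_A = 0.21$ eV
  ($\tau$ shrinks as $T$ rises), and duty-cycled driving through the map
  below. Decay composes exactly as a semigroup, which the tests assert to
  $10^{-12}$.
* **Reads.** Ohmic, non-perturbing, and rectified by a factor $10^4$ for
  reverse bias; sneak paths are assumed fully suppressed by this
  self-rectification (an idealization — no wire resistance or half-select
  scheme is modeled).

Device-to-device variation is sampled as independent lognormal factors
(mean 1, CV 3.87 %) on $G_\mathrm{on}$, $\eta_{16}$ and $\tau_\mathrm{ref}$;
lognormal keeps parameters positive at any CV.

### The duty → τ map

Driving a cell with a duty-cycled pulse train changes its effective decay
constant: measured behavior spans roughly 15 ms at low write/interval (W/I)
ratio to 40 ms at high ratio, with no functional form established. The map
used here is linear through the anchors $\tau(0.15) = 15$ ms and
$\tau(0.85) = 40$ ms, clamped above 0.85 and *extrapolated* (not clamped)
below 0.15, so $\tau(0.05) \approx 11.4$ ms. Clamping below 0.15 would make
the three smallest reservoir duties (0.05, 0.10, 0.15) share one time
constant, collapsing the multi-timescale design the four groups exist for;
extrapolation keeps retention strictly ordered by duty, which is also what
the group-forgetting tests assert.

### The slot-time scale

The printed protocols use 100 µs slots against decay constants of 15–40 ms.
Taken literally, a 20-step sequence spans 4 ms of wall-clock time and the
devices barely forget, which contradicts the strong recency effects the
protocols are meant to display; the actual rest time between slot+read units
on the measurement setup is not printed. The module therefore exposes
`slot_time_scale`: the effective decay interval per step is
(slot + read) × scale. The default, **13** (an effective step of 2.6 ms), is
a modeling choice frozen because it is in the narrow window (≈ 12–13.5)
where all three printed qualitative orderings hold simultaneously for the
20-symbol reference sequence: at duty 0.15 the last symbol "A" wins, at duty
0.85 the most frequent symbol "D" wins, and at intermediate duties "C"
overtakes "D". Below the window the long-term case still favors recency; far
above it the short-term case loses its recency preference. The value is a
reconciliation of printed observations, not a measurement.

## The neuron circuit

The leaky-integrate-and-fire neuron is a series resistor (the synaptic
weight) feeding a node with a parallel capacitor (10 nF) and the memristor
in its off state (100 MΩ leak). During a pulse the membrane voltage relaxes
exponentially toward the divider voltage with time constant
$\tau = C\,(R \parallel R_\mathrm{off})$; between pulses the input is held
at ground and the node discharges with the same constant. The grounded-
interval convention is load-bearing: with a floating input and only the
100 MΩ leak, the neuron would eventually fire at any input frequency,
contradicting the observed refusal at 1600 Hz. Integration is exact
per-segment (no Euler error); `dt` only sets trace sampling density. On
firing, the membrane resets to zero and holds for the remainder of the
pulse — the LRS discharge transient and the output spike waveform are not
modeled, fire events are the output.

The threshold voltage is never printed, so it is calibrated once by
intersecting the feasible intervals implied by the printed spike counts
(4 V, 200 µs pulses): 47 kΩ fires on pulse 3, 94 kΩ on pulse 6, 23.5 kΩ
within 2, a 3200 Hz train within 3, and a 1600 Hz train never. The
closed-form peak recurrence gives the window (2.4132, 2.4654] V; the package
default is its midpoint, ≈ 2.439 V. One printed observation (firing after
two pulses at 47 kΩ in a different figure) is inconsistent with the others
under any single threshold and is treated as an unprinted stimulus variant.

## Reservoir, readout, generator

Each residue of a sequence is one-hot routed into four groups of cells, one
cell per alphabet symbol per group; the groups are driven with W/I duties
0.05/0.10/0.15/0.20 so the same input is remembered on four timescales. A
step potentiates the active cell in every group, decays all cells, and reads
everything, yielding a groups × alphabet feature vector (80-dimensional with
the reference 20-symbol alphabet; 84 with the general 20-residue + end
cursor default — `corpus_alphabet = TRUE` derives the alphabet from the
corpus to reproduce the reference dimensions). Group outputs are equalized
by gains $g = \max_\text{global} / \max_\text{group}$ computed on one
calibration pass over the corpus and frozen before training; applied
features are scaled to a unit maximum.

The readout is in → 500 → out with ReLU hidden activation and softmax
output; with 80/20 that is exactly 50,520 parameters, which is why the
two-weight-matrix reading of the reference description was adopted. Training
is online (batch 1), one cross-entropy gradient step per (feature,
next-symbol) pair including the terminal end-cursor pair, sequences in
corpus order without shuffling (determinism is part of the contract), for 50
epochs by default. The optimizer and learning rate are unstated in the
reference description; Adam with lr $10^{-3}$ was declared as the package
default. Since the reservoir is a fixed deterministic map, per-sequence
features are encoded once and reused across epochs.

Generation seeds the reservoir with a residue, samples the next symbol from
the softmax at temperature 1 (greedy mode exists for tests), feeds it back,
and stops at the end cursor or at a 60-residue cap (reference sequences are
7–48 residues; the cap guarantees termination). Exact duplicates of
training sequences are discarded; an attempt cap bounds the episode.

## Peptide evaluation

Net ("global") charge is a Henderson–Hasselbalch sum over ionizable side
chains (K, R, H positive; D, E, C, Y negative) and both termini, with the
Bjellqvist pKa table at pH 7.0 — the scale used by common peptide-analysis
toolkits. The exact table/pH used for the reference numbers is unstated, so
charges are comparable within the package but not asserted against the
reference means. Molecular weights are Expasy average residue masses plus
one water (monoisotopic switchable), cross-checked against an independent
implementation. Set comparison reports per-set means and the L1 distance
between residue distributions.

## The synthetic corpus

The real training set (1554 AMPs from public databases) is not downloaded.
The generator emulates its stated statistics: lengths uniform on 7–48,
cationic bias targeting a mean global charge of +2.28, and amphipathic
composition approximated by forcing every 4th position to a hydrophobic
residue. The cationic bias is an exponential tilt of a uniform base
distribution along the per-residue charge axis; the tilt parameter is solved
by root finding so the *expected* corpus mean charge equals the target,
given the length distribution and the neutral forced positions. With a few
hundred sequences the sampled mean lands well within the ±0.3 contract
(standard error ≈ 0.1 at n = 500). What the generator does **not** emulate:
real AMP motif grammar, positional charge clustering, length–charge
correlation, or database composition quirks. A green pipeline test therefore
establishes that the system learns *a* sequence distribution with AMP-like
summary statistics, not that it would reproduce the reference corpus
results.

## Numerical choices and degenerate inputs

* All internal units are SI (S, s, K, V, A); constructors accept bench units
  (nS, ms) and conversions happen once at the boundary.
* Time-constant and activation-energy fits are ordinary least squares on the
  log scale; noiseless traces invert exactly (asserted to 1e-9 relative).
* Zero-duration decay, zero-amplitude trains, single-residue sequences,
  empty corpora/sequences, unmapped symbols, sub-threshold set amplitudes,
  and all-baseline calibration passes are all explicit errors or exact
  no-ops, tested as such.
* Softmax is computed with max subtraction; a non-finite training loss is an
  error rather than a silent NaN propagation.
* RNG discipline: corpus generation, weight init, and generation episodes
  take explicit seeds; `sample_device()` and `readout_net()` restore the
  caller's RNG state.

## Known limitations

* The potentiation law, the duty→τ form, the slot-time scale and the
  amplitude scaling are phenomenological reconciliations of printed summary
  numbers, not fitted device physics.
* No sneak-path electrics, wire resistance, endurance degradation, or
  cycle-to-cycle read noise in the protocol paths (cycle CV is carried in
  the parameters but protocol runs are deterministic by default).
* The external AMP-probability predictor used by the reference evaluation is
  out of scope; `volamp` exposes only exact-duplicate removal and
  physicochemical summaries. Reported reference percentages and set means
  are therefore not asserted anywhere in the test suite.
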