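Package: volamp
Title: Volatile-Memristor Reservoir Computing for Antimicrobial Peptide
    Generation
Version: 0.1.0
Authors@R:
    person("volamp", "maintainers", email = "volamp@example.org",
           role = c("aut", "cre"))
Description: Simulator for a neuro-memristive computing stack built on
    gradual titanium-oxide volatile memristors: a phenomenological device
    model (pulse potentiation, exponential self-decay, rectified reads,
    Arrhenius temperature dependence, device-to-device variation), a
    leaky-integrate-and-fire neuron circuit (series resistor, parallel
    capacitor, volatile memristor), crossbar pulse-train protocols for
    binary and symbol-sequence processing, a multi-timescale reservoir
    over the amino-acid alphabet, a trainable softmax readout, and an
    autoregressive generator for antimicrobial-peptide-like sequences.
    Includes peptide physicochemical evaluation (global charge, molecular
    weight, residue composition) and a synthetic cationic peptide corpus
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
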