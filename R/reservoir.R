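# Multi-timescale reservoir front-end over the amino-acid alphabet.
#
# Four groups of memristor cells span the alphabet; each group is driven
# with its own write/interval (W/I) duty ratio, giving it a distinct decay
# time constant. Streaming a residue potentiates its cell in every group;
# the concatenated read currents (group-major) form the feature vector
# consumed by the readout. With the defaults (4 groups x 21 symbols) the
# feature dimension is 84; with a corpus-derived 20-symbol alphabet it is
# the reference 80.

#' Residue alphabet with terminal end cursor
#'
#' The end cursor `"@"` marks sequence termination for training targets and
#' generation; it is always the last symbol and may not occur in input
#' sequences.
#'
#' @param residues Character vector of residue letters (unique, no `"@"`).
#'   Default: the 20 standard amino acids.
#' @return Character vector of class `volamp_alphabet` with `"@"` appended.
#' @export
make_alphabet <- function(residues = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  stopifnot(!anyDuplicated(residues), !"@" %in% residues,
            all(nchar(residues) == 1))
  structure(c(as.character(residues), "@"), class = "volamp_alphabet")
}

#' @rdname make_alphabet
#' @param corpus Character vector of sequences; the alphabet is the sorted
#'   set of residues occurring in it (reference mode: a 19-residue corpus
#'   plus the end cursor gives the 20-symbol alphabet).
#' @export
derive_alphabet <- function(corpus) {
  stopifnot(length(corpus) >= 1)
  make_alphabet(sort(unique(unlist(strsplit(corpus, "")))))
}

#' Reservoir configuration
#'
#' @param duties W/I duty ratios of the memristor groups. Default
#'   `c(0.05, 0.10, 0.15, 0.20)`.
#' @param set_amplitude Set amplitude (V). Default 4.
#' @param unit_slot Unit slot length (s). Default 100 us.
#' @param read_v,read_width Read pulse: 1.5 V, 100 us.
#' @param slot_time_scale Effective-decay multiplier, as in
#'   [crossbar_array()]. Default 13.
#' @param params A [device_params()].
#' @return Object of class `reservoir_config`.
#' @export
reservoir_config <- function(duties = c(0.05, 0.10, 0.15, 0.20),
                             set_amplitude = 4, unit_slot = 100e-6,
                             read_v = 1.5, read_width = 100e-6,
                             slot_time_scale = 13,
                             params = device_params()) {
  stopifnot(length(duties) >= 1, !anyDuplicated(duties),
            all(duties > 0), all(duties < 1), slot_time_scale > 0)
  structure(list(duties = duties, set_amplitude = set_amplitude,
                 unit_slot = unit_slot, read_v = read_v,
                 read_width = read_width, slot_time_scale = slot_time_scale,
                 params = params), class = "reservoir_config")
}

#' Initialize a reservoir state
#'
#' Precomputes each group's per-slot potentiation gain and decay factor so
#' that [encode_step()] is a cheap vector update.
#'
#' @param config A [reservoir_config()].
#' @param alphabet A [make_alphabet()] vector.
#' @return Object of class `reservoir_state`.
#' @export
reservoir_init <- function(config, alphabet) {
  stopifnot(inherits(config, "reservoir_config"))
  g <- length(config$duties); a <- length(alphabet)
  eta <- vapply(config$duties, function(d)
    pulse_gain(pulse_spec(config$set_amplitude, d * config$unit_slot, "set"),
               config$params), numeric(1))
  dt <- (config$unit_slot + config$read_width) * config$slot_time_scale
  dec <- vapply(config$duties, function(d)
    exp(-dt / tau_effective(config$params, d)), numeric(1))
  structure(list(
    w = matrix(0, g, a, dimnames = list(NULL, alphabet)),
    t = 0, eta = eta, decay = dec, config = config,
    alphabet = alphabet
  ), class = "reservoir_state")
}

#' Reset the reservoir to its initial state
#'
#' All cells return to the baseline state and the clock is zeroed.
#'
#' @param state A `reservoir_state`.
#' @return The reset state.
#' @export
reservoir_reset <- function(state) {
  state$w[] <- 0
  state$t <- 0
  state
}

#' Stream one symbol through the reservoir
#'
#' In each group the cell of `symbol` receives one duty-cycled set slot;
#' every cell decays with its group's time constant over the slot plus read,
#' and all group x alphabet read currents are returned concatenated
#' group-major.
#'
#' @param state A `reservoir_state`.
#' @param symbol A single symbol present in the alphabet.
#' @return List with the updated `state` and the raw `features` (amperes),
#'   length `groups * alphabet`.
#' @export
encode_step <- function(state, symbol) {
  j <- match(symbol, state$alphabet)
  if (is.na(j)) stop("symbol '", symbol, "' is not in the alphabet")
  state$w[, j] <- state$w[, j] + state$eta * (1 - state$w[, j])
  state$w <- state$w * state$decay  # recycles per-row (per-group) factors
  state$t <- state$t +
    (state$config$unit_slot + state$config$read_width) * state$config$slot_time_scale
  p <- state$config$params
  g_mat <- p$g_off + state$w * (p$g_on - p$g_off)
  features <- as.vector(t(g_mat)) * state$config$read_v
  names(features) <- paste0("g", rep(seq_along(state$eta) - 1,
                                     each = length(state$alphabet)),
                            "_", rep(state$alphabet, length(state$eta)))
  list(state = state, features = features)
}

#' Encode a whole sequence into a feature matrix
#'
#' Streams the residues of `sequence` through a fresh (or supplied)
#' reservoir; row i holds the raw feature vector after residue i.
#'
#' @param x A `reservoir_config` (fresh state) or `reservoir_state`.
#' @param sequence Single string or character vector of symbols.
#' @param alphabet Required when `x` is a config.
#' @return List with `features` (steps x groups*alphabet matrix) and the
#'   final `state`.
#' @export
encode_sequence <- function(x, sequence, alphabet = NULL) {
  state <- if (inherits(x, "reservoir_state")) x else {
    stopifnot(!is.null(alphabet))
    reservoir_init(x, alphabet)
  }
  syms <- if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    strsplit(sequence, "")[[1]] else as.character(sequence)
  stopifnot(length(syms) >= 1)
  out <- matrix(NA_real_, length(syms),
                length(state$eta) * length(state$alphabet))
  for (i in seq_along(syms)) {
    res <- encode_step(state, syms[i])
    state <- res$state
    out[i, ] <- res$features
  }
  colnames(out) <- names(res$features)
  list(features = out, state = state)
}

#' Next-symbol training pairs for one sequence
#'
#' The target is the sequence shifted left by one residue with the end
#' cursor appended, e.g. `"KAIST"` gives inputs K,A,I,S,T and targets
#' A,I,S,T,@.
#'
#' @param sequence Non-empty residue string.
#' @param alphabet A [make_alphabet()] vector.
#' @return `data.frame` with columns `input` and `target`.
#' @export
make_training_pairs <- function(sequence, alphabet) {
  stopifnot(length(sequence) == 1, nchar(sequence) >= 1)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% setdiff(alphabet, "@"))
  if (length(bad))
    stop(sprintf("residue '%s' at position %d is not in the alphabet",
                 chars[bad[1]], bad[1]))
  data.frame(input = chars, target = c(chars[-1], "@"),
             stringsAsFactors = FALSE)
}

#' Fit per-group amplification gains
#'
#' Computed on a calibration pass over raw feature vectors: each group's
#' gain is `global_max / group_max` (invariant to global rescaling of the
#' features), and the stored `scale` equals the global maximum, so applied
#' features are unitless with every group's maximum equal to 1.
#'
#' @param features Matrix (steps x groups*alphabet) of raw features.
#' @param n_groups Number of memristor groups.
#' @param baseline Baseline feature level (current of an unpotentiated cell);
#'   an all-baseline calibration pass is an error.
#' @return List of class `group_gains` with `gains`, `scale`, `n_groups`,
#'   `block`.
#' @export
fit_group_gains <- function(features, n_groups, baseline = NULL) {
  features <- rbind(features)
  stopifnot(ncol(features) %% n_groups == 0)
  block <- ncol(features) / n_groups
  gmax <- vapply(seq_len(n_groups), function(g)
    max(features[, (g - 1) * block + seq_len(block)]), numeric(1))
  if (is.null(baseline)) baseline <- min(features)
  if (all(gmax <= baseline * (1 + 1e-12)))
    stop("all features are at baseline; nothing to calibrate")
  global <- max(gmax)
  structure(list(gains = global / gmax, scale = global,
                 n_groups = n_groups, block = block),
            class = "group_gains")
}

#' Apply group gains to raw features
#'
#' @param features Raw feature vector or matrix.
#' @param gg A `group_gains` object.
#' @return Unitless features with per-group maxima normalized to 1 (on the
#'   calibration data).
#' @export
apply_group_gains <- function(features, gg) {
  mult <- rep(gg$gains, each = gg$block) / gg$scale
  if (is.matrix(features)) sweep(features, 2, mult, "*")
  else features * mult
}
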