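# Synthetic AMP-like corpus generator. Emulates the statistical structure of
# the reference training set (1554 antimicrobial peptides, ~7-48 residues,
# cationic with mean global charge about +2.28, amphipathic composition)
# without any external download. The mechanism is exponential tilting of a
# base residue distribution along the per-residue charge axis, solved so the
# expected corpus mean charge hits the target; amphipathicity is emulated by
# forcing every `amphipathic_period`-th position to a hydrophobic residue.

#' Specification of a synthetic AMP-like corpus
#'
#' @param n_sequences Number of sequences. Default 1554 (the reference
#'   corpus size); tests use a few hundred for speed.
#' @param length_range Integer range of sequence lengths, drawn uniformly.
#'   Default `c(7, 48)`.
#' @param target_charge Target corpus mean global charge at pH 7 (elementary
#'   charges). Default +2.28.
#' @param hydrophobic Residues used for the periodic hydrophobic placement.
#' @param amphipathic_period Every `period`-th position is hydrophobic; 0
#'   disables the placement. Default 4.
#' @param seed Integer seed.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_sequences = 1554, length_range = c(7, 48),
                        target_charge = 2.28,
                        hydrophobic = c("A", "F", "I", "L", "M", "V", "W"),
                        amphipathic_period = 4, seed = 1) {
  stopifnot(n_sequences >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            is.finite(target_charge), amphipathic_period >= 0,
            all(hydrophobic %in% .aa20))
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 target_charge = target_charge, hydrophobic = hydrophobic,
                 amphipathic_period = as.integer(amphipathic_period),
                 seed = as.integer(seed)), class = "corpus_spec")
}

# Side-chain charge contribution of each residue at the model's pH.
.residue_charges <- function(model = charge_model()) {
  pos <- function(pka) 1 / (1 + 10^(model$pH - pka))
  neg <- function(pka) 1 / (1 + 10^(pka - model$pH))
  q <- stats::setNames(numeric(20), .aa20)
  q["K"] <- pos(model$pKa["K"]); q["R"] <- pos(model$pKa["R"])
  q["H"] <- pos(model$pKa["H"])
  q["D"] <- -neg(model$pKa["D"]); q["E"] <- -neg(model$pKa["E"])
  q["C"] <- -neg(model$pKa["C"]); q["Y"] <- -neg(model$pKa["Y"])
  q
}

#' Generate a synthetic AMP-like corpus
#'
#' Lengths are uniform over `length_range`. Free positions draw residues
#' from a uniform base distribution exponentially tilted along per-residue
#' charge, with the tilt solved (by 1-D root finding) so that the expected
#' corpus mean global charge equals `target_charge`; an unreachable target
#' is an error. Deterministic given the seed; the end cursor never occurs.
#'
#' @param spec A [corpus_spec()].
#' @param model A [charge_model()] used for the calibration (pH 7 default).
#' @return Character vector of sequences.
#' @export
generate_corpus <- function(spec, model = charge_model()) {
  stopifnot(inherits(spec, "corpus_spec"))
  q <- .residue_charges(model)
  lens <- seq(spec$length_range[1], spec$length_range[2])
  n_h <- if (spec$amphipathic_period > 0)
    floor(lens / spec$amphipathic_period) else rep(0, length(lens))
  e_len <- mean(lens)
  e_h <- mean(n_h)
  e_free <- e_len - e_h
  q_term <- global_charge(paste(rep("G", 2), collapse = ""), model) # termini only
  q_hbar <- mean(q[spec$hydrophobic])
  needed <- (spec$target_charge - q_term - e_h * q_hbar) / e_free
  if (needed <= min(q) || needed >= max(q))
    stop(sprintf("target charge %.3g is infeasible for the length range",
                 spec$target_charge))
  tilt_mean <- function(beta) {
    p <- exp(beta * q); p <- p / sum(p); sum(p * q)
  }
  beta <- stats::uniroot(function(b) tilt_mean(b) - needed, c(-80, 80),
                         tol = 1e-12)$root
  p_tilt <- exp(beta * q); p_tilt <- p_tilt / sum(p_tilt)

  set.seed(spec$seed)
  vapply(seq_len(spec$n_sequences), function(i) {
    len <- sample(lens, 1)
    chars <- sample(.aa20, len, replace = TRUE, prob = p_tilt)
    if (spec$amphipathic_period > 0) {
      idx <- which(seq_len(len) %% spec$amphipathic_period == 0)
      if (length(idx))
        chars[idx] <- sample(spec$hydrophobic, length(idx), replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' In-reference fixtures
#'
#' The printed inputs reused throughout the test protocols: the magainin-2
#' sequence, the 20-step A-D symbol sequence of the duty-cycle experiment,
#' and the seven 4-bit binary patterns.
#'
#' @return Named list with `magainin2` (string), `symbol_sequence`
#'   (character vector of length 20) and `binary_patterns` (list of seven
#'   0/1 vectors).
#' @export
amp_fixtures <- function() {
  list(
    magainin2 = "GIGKFLHSAKKFGKAFVGEIMNS",
    symbol_sequence = c("D", "D", "D", "C", "C", "B", "D", "C", "C", "D",
                       "B", "A", "D", "B", "A", "C", "D", "C", "B", "A"),
    binary_patterns = list(c(1, 1, 1, 1), c(1, 1, 0, 1), c(0, 0, 0, 1),
                          c(1, 1, 1, 0), c(0, 0, 1, 0), c(1, 0, 0, 0),
                          c(0, 0, 0, 0))
  )
}
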