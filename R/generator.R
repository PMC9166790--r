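# Autoregressive sequence generation: seed residue -> reservoir -> softmax
# readout -> sample -> feed back, until the end cursor is drawn or the
# length cap is hit. Generated duplicates of training sequences are removed
# (exact string match).

#' Generate one sequence from a trained model
#'
#' The reservoir starts from its initial state; at every step the sampled
#' symbol is fed back as the next input. Sampling is at temperature 1
#' directly from the softmax probabilities; `greedy = TRUE` (argmax) is a
#' deterministic mode used mainly for testing.
#'
#' @param model A `volamp_model` from [fit_readout()].
#' @param seed_residue Single residue to start from; not the end cursor.
#' @param max_len Length cap guaranteeing termination. Default 60.
#' @param greedy Use argmax instead of sampling.
#' @param rng_seed Optional integer; seeds the sampler for a reproducible
#'   run (otherwise the current RNG stream is used).
#' @return Object of class `generation_run`: `sequence`, `seed`,
#'   `stop_reason` ("end_cursor" or "max_len").
#' @export
generate_one <- function(model, seed_residue, max_len = 60, greedy = FALSE,
                         rng_seed = NULL) {
  alphabet <- model$alphabet
  if (identical(seed_residue, "@")) stop("seed must not be the end cursor")
  if (!seed_residue %in% alphabet)
    stop("seed residue '", seed_residue, "' is not in the alphabet")
  stopifnot(max_len >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  state <- reservoir_init(model$config, alphabet)
  chars <- seed_residue
  sym <- seed_residue
  stop_reason <- "max_len"
  repeat {
    res <- encode_step(state, sym)
    state <- res$state
    p <- forward(model$net, apply_group_gains(res$features, model$gains))
    nxt <- if (greedy) alphabet[which.max(p)] else sample(alphabet, 1, prob = p)
    if (nxt == "@") { stop_reason <- "end_cursor"; break }
    if (length(chars) >= max_len) break
    chars <- c(chars, nxt)
    sym <- nxt
  }
  structure(list(sequence = paste(chars, collapse = ""), seed = seed_residue,
                 stop_reason = stop_reason), class = "generation_run")
}

#' Generate a deduplicated set of sequences
#'
#' Seeds are cycled in order (by convention, the first residues of the
#' training sequences); generation continues until `n` retained sequences or
#' the attempt cap is reached (then a warning and a partial set). A sequence
#' is retained unless it exactly matches a training sequence.
#'
#' @param model A `volamp_model`.
#' @param n Number of sequences to retain.
#' @param seeds Character vector of seed residues; default: first residues
#'   of `training_corpus`.
#' @param training_corpus Sequences used for exact-duplicate removal.
#' @param rng_seed Integer seed for the whole generation episode.
#' @param max_len Per-sequence length cap.
#' @param max_attempts Attempt cap. Default `10 * n`.
#' @return Character vector of retained sequences with attributes
#'   `stop_reasons`, `seeds` and `attempts`.
#' @export
generate_set <- function(model, n, seeds = NULL, training_corpus = character(),
                         rng_seed = 1, max_len = 60, max_attempts = 10 * n) {
  stopifnot(n >= 1)
  if (is.null(seeds)) {
    stopifnot(length(training_corpus) >= 1)
    seeds <- substr(training_corpus, 1, 1)
  }
  stopifnot(length(seeds) >= 1)
  set.seed(rng_seed)
  kept <- character(0); reasons <- character(0); used <- character(0)
  attempts <- 0
  while (length(kept) < n && attempts < max_attempts) {
    attempts <- attempts + 1
    sd <- seeds[((attempts - 1) %% length(seeds)) + 1]
    run <- generate_one(model, sd, max_len = max_len)
    if (!run$sequence %in% training_corpus) {
      kept <- c(kept, run$sequence)
      reasons <- c(reasons, run$stop_reason)
      used <- c(used, sd)
    }
  }
  if (length(kept) < n)
    warning("attempt cap reached: returning ", length(kept), " of ", n,
            " requested sequences")
  structure(kept, stop_reasons = reasons, seeds = used, attempts = attempts)
}

#' Write generation results as FASTA
#'
#' Headers follow `>gen_<i> seed=<X> stop=<reason>`.
#'
#' @param sequences Character vector from [generate_set()] (attributes used
#'   when present).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generated_fasta <- function(sequences, path) {
  reasons <- attr(sequences, "stop_reasons")
  seeds <- attr(sequences, "seeds")
  if (is.null(reasons)) reasons <- rep("end_cursor", length(sequences))
  if (is.null(seeds)) seeds <- substr(sequences, 1, 1)
  headers <- sprintf("gen_%d seed=%s stop=%s", seq_along(sequences), seeds,
                     reasons)
  write_fasta(as.character(sequences), path, headers = headers)
}
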