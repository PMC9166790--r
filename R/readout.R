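# Trainable readout: a two-weight-matrix perceptron (in -> 500 -> out) with
# a ReLU hidden layer and softmax output, trained online (batch 1) by
# next-symbol cross-entropy with Adam. In reference mode (in = 80, out = 20)
# the parameter count is exactly 50,520. The wording "80 x 500 x 20 MLP with
# ReLU on the first and second layers" is read as two weight matrices (the
# only reading consistent with that parameter count), with ReLU applied to
# the single hidden layer.

#' Construct a readout network
#'
#' Weights are initialized from a fan-in-scaled uniform distribution,
#' `U(-1, 1)/sqrt(fan_in)`; biases start at zero. Adam moment buffers are
#' carried inside the object so training is a pure fold over steps.
#'
#' @param n_in Input dimension (groups x alphabet).
#' @param n_hidden Hidden width. Default 500.
#' @param n_out Output dimension (alphabet size).
#' @param seed Integer seed for the weight draw.
#' @return Object of class `readout_net`.
#' @export
readout_net <- function(n_in, n_hidden = 500, n_out, seed = 1) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w1 <- matrix(stats::runif(n_in * n_hidden, -1, 1) / sqrt(n_in), n_in, n_hidden)
  w2 <- matrix(stats::runif(n_hidden * n_out, -1, 1) / sqrt(n_hidden), n_hidden, n_out)
  net <- list(w1 = w1, b1 = numeric(n_hidden), w2 = w2, b2 = numeric(n_out),
              n_in = n_in, n_hidden = n_hidden, n_out = n_out,
              adam = NULL, step = 0L)
  class(net) <- "readout_net"
  net
}

#' Number of trainable parameters
#'
#' `n_in * h + h + h * n_out + n_out`; 50,520 for the reference 80-500-20
#' network.
#'
#' @param net A [readout_net()].
#' @return Integer count.
#' @export
count_parameters <- function(net) {
  length(net$w1) + length(net$b1) + length(net$w2) + length(net$b2)
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Forward pass
#'
#' @param net A [readout_net()].
#' @param features Numeric vector of length `n_in` (gain-normalized reservoir
#'   output).
#' @return Probability vector over the alphabet (sums to 1).
#' @export
forward <- function(net, features) {
  if (length(features) != net$n_in)
    stop("feature length ", length(features), " != network input ", net$n_in)
  h <- pmax(drop(features %*% net$w1) + net$b1, 0)
  .softmax(drop(h %*% net$w2) + net$b2)
}

# forward keeping the hidden activations for backprop
.forward_cache <- function(net, x) {
  h <- pmax(drop(x %*% net$w1) + net$b1, 0)
  p <- .softmax(drop(h %*% net$w2) + net$b2)
  list(h = h, p = p)
}

.adam_init <- function(net) {
  z <- function(x) x * 0
  list(m = list(w1 = z(net$w1), b1 = z(net$b1), w2 = z(net$w2), b2 = z(net$b2)),
       v = list(w1 = z(net$w1), b1 = z(net$b1), w2 = z(net$w2), b2 = z(net$b2)))
}

#' One online training step
#'
#' Cross-entropy `-log p(target)` with an Adam update (defaults: lr 1e-3,
#' beta1 0.9, beta2 0.999).
#'
#' @param net A [readout_net()].
#' @param features Input vector of length `n_in`.
#' @param target Index of the target symbol in the output alphabet.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam hyper-parameters.
#' @return List with the updated `net` and the scalar `loss`.
#' @export
train_step <- function(net, features, target, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(target >= 1, target <= net$n_out)
  fc <- .forward_cache(net, features)
  loss <- -log(fc$p[target])
  if (!is.finite(loss)) stop("non-finite training loss")
  dlogits <- fc$p
  dlogits[target] <- dlogits[target] - 1
  dh <- drop(net$w2 %*% dlogits)
  dh[fc$h <= 0] <- 0
  grads <- list(w1 = outer(unname(features), dh), b1 = dh,
                w2 = outer(fc$h, dlogits), b2 = dlogits)
  if (is.null(net$adam)) net$adam <- .adam_init(net)
  net$step <- net$step + 1L
  t <- net$step
  for (nm in names(grads)) {
    net$adam$m[[nm]] <- beta1 * net$adam$m[[nm]] + (1 - beta1) * grads[[nm]]
    net$adam$v[[nm]] <- beta2 * net$adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- net$adam$m[[nm]] / (1 - beta1^t)
    vhat <- net$adam$v[[nm]] / (1 - beta2^t)
    net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, loss = loss)
}

#' Train the full reservoir + readout system on a corpus
#'
#' For every sequence the reservoir is reset and streamed residue by
#' residue; each step yields one (feature, next-symbol) training pair,
#' including the final (last residue, end-cursor) pair. The reservoir is a
#' fixed deterministic map, so per-sequence features are computed once and
#' reused across epochs. Group amplification gains are frozen after a
#' calibration pass over the whole corpus before the first epoch.
#'
#' @param corpus Character vector of residue sequences.
#' @param config A [reservoir_config()].
#' @param alphabet Alphabet to use; `NULL` selects the standard 20 amino
#'   acids plus the end cursor, or the corpus-derived alphabet when
#'   `corpus_alphabet = TRUE`.
#' @param corpus_alphabet Derive the alphabet from the corpus (reference
#'   mode; a 19-residue corpus gives the 20-symbol alphabet and the 80-dim
#'   feature).
#' @param epochs Number of passes over the corpus. Default 50.
#' @param lr Adam learning rate. Default 1e-3.
#' @param n_hidden Hidden width. Default 500.
#' @param seed Integer seed (weight initialization).
#' @param verbose Print per-epoch losses.
#' @return Object of class `volamp_model`: `net`, `gains`, `alphabet`,
#'   `config`, `loss_history` (mean cross-entropy per epoch).
#' @export
fit_readout <- function(corpus, config = reservoir_config(), alphabet = NULL,
                        corpus_alphabet = FALSE, epochs = 50, lr = 1e-3,
                        n_hidden = 500, seed = 1, verbose = FALSE) {
  stopifnot(length(corpus) >= 1, epochs >= 1)
  empty <- nchar(corpus) == 0
  if (any(empty)) {
    warning(sum(empty), " empty sequence(s) skipped")
    corpus <- corpus[!empty]
  }
  stopifnot(length(corpus) >= 1)
  if (is.null(alphabet))
    alphabet <- if (corpus_alphabet) derive_alphabet(corpus) else make_alphabet()

  # calibration pass: encode every sequence once, cache features and targets
  enc <- lapply(corpus, function(s) {
    pairs <- make_training_pairs(s, alphabet)
    feats <- encode_sequence(config, s, alphabet)$features
    list(features = feats, targets = match(pairs$target, alphabet))
  })
  gains <- fit_group_gains(do.call(rbind, lapply(enc, `[[`, "features")),
                           n_groups = length(config$duties))
  for (i in seq_along(enc))
    enc[[i]]$features <- apply_group_gains(enc[[i]]$features, gains)

  net <- readout_net(n_in = length(config$duties) * length(alphabet),
                     n_hidden = n_hidden, n_out = length(alphabet),
                     seed = seed)
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0; nstep <- 0
    for (e in enc) {
      for (k in seq_along(e$targets)) {
        st <- train_step(net, e$features[k, ], e$targets[k], lr = lr)
        net <- st$net
        tot <- tot + st$loss; nstep <- nstep + 1
      }
    }
    loss_history[ep] <- tot / nstep
    if (verbose)
      message(sprintf("epoch %d/%d mean loss %.4f", ep, epochs, loss_history[ep]))
  }
  structure(list(net = net, gains = gains, alphabet = alphabet,
                 config = config, loss_history = loss_history,
                 lr = lr, epochs = epochs, seed = seed),
            class = "volamp_model")
}

#' @export
print.volamp_model <- function(x, ...) {
  cat(sprintf("volamp model: %d-%d-%d readout (%d parameters), %d groups x %d symbols\n",
              x$net$n_in, x$net$n_hidden, x$net$n_out, count_parameters(x$net),
              length(x$config$duties), length(x$alphabet)))
  cat(sprintf("  trained %d epoch(s), final mean loss %.4f\n",
              x$epochs, utils::tail(x$loss_history, 1)))
  invisible(x)
}
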