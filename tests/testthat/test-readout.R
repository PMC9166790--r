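test_that("parameter count follows the two-weight-matrix formula", {
  expect_identical(count_parameters(readout_net(80, 500, 20)), 50520L)
  expect_identical(count_parameters(readout_net(1, 500, 1)), 1501L)
  # brute-force enumeration of stored scalars for random shapes
  set.seed(3)
  for (i in 1:5) {
    n_in <- sample(2:30, 1); h <- sample(2:40, 1); n_out <- sample(2:10, 1)
    net <- readout_net(n_in, h, n_out)
    expect_identical(count_parameters(net),
                     as.integer(n_in * h + h + h * n_out + n_out))
  }
})

test_that("forward produces a probability simplex with softmax invariances", {
  net <- readout_net(6, 8, 4, seed = 2)
  set.seed(10)
  for (i in 1:20) {
    p <- forward(net, runif(6))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  # zero net: uniform output
  z <- readout_net(6, 8, 4)
  z$w1[] <- 0; z$b1[] <- 0; z$w2[] <- 0; z$b2[] <- 0
  expect_equal(forward(z, runif(6)), rep(0.25, 4), tolerance = 1e-12)
  # shifting all output biases leaves the softmax unchanged
  net2 <- net; net2$b2 <- net2$b2 + 5
  x <- runif(6)
  expect_equal(forward(net, x), forward(net2, x), tolerance = 1e-12)
  expect_error(forward(net, runif(5)), "feature length")
})

test_that("analytic gradients match finite differences on a tiny net", {
  net <- readout_net(4, 5, 3, seed = 7)
  x <- c(0.3, -0.2, 0.8, 0.5)
  target <- 2L
  # numerical gradient via central differences on every parameter
  fc_loss <- function(n) {
    h <- pmax(drop(x %*% n$w1) + n$b1, 0)
    z <- drop(h %*% n$w2) + n$b2
    e <- exp(z - max(z)); p <- e / sum(e)
    -log(p[target])
  }
  # analytic gradient reproduced from one SGD-like probe: run train_step with
  # plain gradient extraction by comparing against numeric derivatives
  eps <- 1e-6
  num_grad <- function(field) {
    g <- array(0, dim = if (is.matrix(net[[field]])) dim(net[[field]]) else length(net[[field]]))
    for (i in seq_along(net[[field]])) {
      np <- net; np[[field]][i] <- np[[field]][i] + eps
      nm <- net; nm[[field]][i] <- nm[[field]][i] - eps
      g[i] <- (fc_loss(np) - fc_loss(nm)) / (2 * eps)
    }
    g
  }
  # recompute the analytic gradient exactly as train_step does
  h <- pmax(drop(x %*% net$w1) + net$b1, 0)
  z <- drop(h %*% net$w2) + net$b2
  e <- exp(z - max(z)); p <- e / sum(e)
  dlogits <- p; dlogits[target] <- dlogits[target] - 1
  dh <- drop(net$w2 %*% dlogits); dh[h <= 0] <- 0
  expect_equal(as.vector(outer(x, dh)), as.vector(num_grad("w1")), tolerance = 1e-5)
  expect_equal(as.vector(dh), as.vector(num_grad("b1")), tolerance = 1e-5)
  expect_equal(as.vector(outer(h, dlogits)), as.vector(num_grad("w2")), tolerance = 1e-5)
  expect_equal(as.vector(dlogits), as.vector(num_grad("b2")), tolerance = 1e-5)
})

test_that("repeated steps on one example drive its probability toward 1", {
  net <- readout_net(4, 6, 3, seed = 1)
  x <- c(1, 0.5, 0, 0.2)
  losses <- numeric(300)
  for (i in seq_len(300)) {
    st <- train_step(net, x, 1L, lr = 1e-2)
    net <- st$net; losses[i] <- st$loss
  }
  expect_lt(losses[300], 0.01)
  # monotone after warm-up
  expect_true(all(diff(losses[50:300]) <= 1e-8))
  expect_equal(-log(forward(net, x)[1]), losses[300], tolerance = 1e-2)
})

test_that("training is deterministic and learns a toy grammar", {
  corpus <- rep(c("ABC", "ABC", "CAB"), 4)
  cfg <- reservoir_config()
  m1 <- fit_readout(corpus, cfg, corpus_alphabet = TRUE, epochs = 5, seed = 9)
  m2 <- fit_readout(corpus, cfg, corpus_alphabet = TRUE, epochs = 5, seed = 9)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_length(m1$loss_history, 5)
  # deterministic grammar: after enough epochs next-symbol argmax is exact
  m <- fit_readout(rep("ABC", 8), cfg, corpus_alphabet = TRUE, epochs = 40,
                   seed = 4)
  enc <- encode_sequence(m$config, "ABC", m$alphabet)
  f <- apply_group_gains(enc$features, m$gains)
  preds <- vapply(1:3, function(k) m$alphabet[which.max(forward(m$net, f[k, ]))],
                  character(1))
  expect_identical(preds, c("B", "C", "@"))
})

test_that("empty sequences are skipped with a warning and epochs validated", {
  expect_warning(m <- fit_readout(c("KAIST", ""), epochs = 1), "skipped")
  expect_length(m$loss_history, 1)
  expect_error(fit_readout("KAIST", epochs = 0))
})

test_that("checkpoints round-trip through JSON", {
  m <- fit_readout(rep("KAIST", 4), corpus_alphabet = TRUE, epochs = 2, seed = 5)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$net$w1, m$net$w1, tolerance = 1e-12)
  expect_identical(as.character(m2$alphabet), as.character(m$alphabet))
  expect_equal(m2$gains$gains, unname(m$gains$gains), tolerance = 1e-12)
  x <- runif(m$net$n_in)
  expect_equal(forward(m2$net, x), forward(m$net, x), tolerance = 1e-12)
  unlink(path)
})
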