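test_that("alphabets are well-formed with the end cursor last", {
  ab <- make_alphabet()
  expect_length(ab, 21)
  expect_identical(ab[[21]], "@")
  expect_error(make_alphabet(c("A", "A")))
  expect_error(make_alphabet(c("A", "@")))
  # corpus-derived alphabet (reference mode): 19 residues -> 20 symbols
  fx <- amp_fixtures()
  ab2 <- derive_alphabet(fx$magainin2)
  expect_identical(ab2[[length(ab2)]], "@")
  expect_true(all(strsplit(fx$magainin2, "")[[1]] %in% ab2))
})

test_that("training pairs shift left and append the end cursor", {
  ab <- make_alphabet()
  pairs <- make_training_pairs("KAIST", ab)
  expect_identical(pairs$input, c("K", "A", "I", "S", "T"))
  expect_identical(pairs$target, c("A", "I", "S", "T", "@"))

  fx <- amp_fixtures()
  pm <- make_training_pairs(fx$magainin2, ab)
  expect_identical(paste(pm$target, collapse = ""), "IGKFLHSAKKFGKAFVGEIMNS@")
  expect_equal(nrow(pm), nchar(fx$magainin2))

  expect_identical(make_training_pairs("G", ab)$target, "@")
  expect_error(make_training_pairs("GBZ", ab), "position 2")
})

test_that("encode_step potentiates the right cells and carries state", {
  ab <- make_alphabet()
  cfg <- reservoir_config()
  st <- reservoir_init(cfg, ab)
  res <- encode_step(st, "G")
  baseline <- min(res$features)
  expect_length(res$features, 4 * 21)
  # exactly 4 entries (one per group) above baseline
  expect_equal(sum(res$features > baseline * (1 + 1e-9)), 4)
  expect_true(all(res$features >= 0))
  # repeated same symbol: monotone growth of its entries
  st2 <- res$state
  prev <- res$features
  for (i in 1:5) {
    r <- encode_step(st2, "G")
    idx <- which(r$features > baseline * (1 + 1e-9))
    expect_true(all(r$features[idx] >= prev[idx]))
    prev <- r$features; st2 <- r$state
  }
  expect_error(encode_step(st, "@@"), "not in the alphabet")
})

test_that("order matters: AC and CA give different final features", {
  ab <- make_alphabet()
  cfg <- reservoir_config()
  fa <- encode_sequence(cfg, "AC", ab)$features
  fb <- encode_sequence(cfg, "CA", ab)$features
  expect_false(isTRUE(all.equal(fa[2, ], fb[2, ])))
})

test_that("reset restores the initial state exactly", {
  ab <- make_alphabet()
  cfg <- reservoir_config()
  st <- encode_sequence(cfg, "KAIST", ab)$state
  rs <- reservoir_reset(st)
  expect_true(all(rs$w == 0))
  expect_equal(rs$t, 0)
  expect_identical(reservoir_reset(rs), rs)
  # encode after reset equals encode on a fresh state
  f1 <- encode_step(rs, "K")$features
  f2 <- encode_step(reservoir_init(cfg, ab), "K")$features
  expect_identical(f1, f2)
})

test_that("smaller duty means faster forgetting, ordered across groups", {
  ab <- make_alphabet()
  cfg <- reservoir_config()
  # pulse K once, then stream other symbols; track K's cells across groups
  st <- encode_step(reservoir_init(cfg, ab), "K")$state
  kcols <- which(ab == "K")
  w0 <- st$w[, kcols]
  for (i in 1:5) st <- encode_step(st, "A")$state
  ratio <- st$w[, kcols] / w0
  # contribution decreasing in elapsed steps and retention ordered by duty
  expect_true(all(ratio < 1))
  expect_true(all(diff(ratio) > 0)) # duties are increasing across groups
})

test_that("single-group replay separates the seven binary patterns", {
  fx <- amp_fixtures()
  cfg <- reservoir_config(duties = 0.2)
  ab <- structure(c("1", "0", "@"), class = "volamp_alphabet")
  finals <- vapply(fx$binary_patterns, function(b) {
    f <- encode_sequence(cfg, as.character(b), ab)$features
    paste(signif(f[nrow(f), ], 12), collapse = ",")
  }, character(1))
  expect_equal(length(unique(finals)), 7)
})

test_that("group gains equalize per-group maxima and are scale-invariant", {
  ab <- make_alphabet()
  cfg <- reservoir_config()
  feats <- encode_sequence(cfg, "KAISTKAIST", ab)$features
  gg <- fit_group_gains(feats, n_groups = 4)
  scaled <- apply_group_gains(feats, gg)
  block <- ncol(feats) / 4
  maxima <- vapply(1:4, function(g)
    max(scaled[, (g - 1) * block + seq_len(block)]), numeric(1))
  expect_equal(maxima, rep(1, 4), tolerance = 1e-12)
  # gains invariant to global rescaling of the raw features
  gg2 <- fit_group_gains(feats * 1e6, n_groups = 4)
  expect_equal(gg$gains, gg2$gains, tolerance = 1e-12)
  # single group: gain 1
  gg1 <- fit_group_gains(feats[, seq_len(block)], n_groups = 1)
  expect_equal(unname(gg1$gains), 1)
  # all-baseline features: error
  expect_error(fit_group_gains(matrix(55e-9 * 1.5, 2, 84), n_groups = 4),
               "baseline")
})
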