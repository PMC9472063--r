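test_that("tokenize pads, truncates and maps unknowns", {
  v <- tiny_vocab()
  b <- tokenize(c("a", "b", "c"), v, 8)
  expect_length(b$ids, 8)
  expect_equal(b$mask, c(1, 1, 1, 0, 0, 0, 0, 0))
  expect_false(b$truncated)
  b2 <- tokenize(rep("a", 10), v, 8)
  expect_equal(b2$length, 8)
  expect_true(b2$truncated)
  b3 <- tokenize(c("a", "ZZZ"), v, 4)
  expect_equal(b3$ids[2], 2L)  # <unk>
  expect_error(tokenize(character(0), v, 4), "empty")
  expect_error(tokenize("a", c("x", "y"), 4), "reserve")
})

test_that("embedding output is the sum of the three embedding tables", {
  enc <- tiny_encoder(n_layers = 0)
  b <- tokenize(c("a", "a"), tiny_vocab(), 6)
  # zero out word and type tables: embedding equals position embedding
  enc0 <- enc
  enc0$par$tok_emb[] <- 0
  enc0$par$type_emb[] <- 0
  fwd <- encoder_forward(enc0, b)
  expect_equal(fwd$E, enc0$par$pos_emb)
  # identical tokens at different positions differ by the position term
  fwd2 <- encoder_forward(enc, b)
  expect_false(isTRUE(all.equal(fwd2$E[1, ], fwd2$E[2, ])))
  # with no layers, features equal embeddings
  expect_equal(fwd2$features, fwd2$E)
  # deterministic on repeat call
  expect_identical(encoder_forward(enc, b)$emissions, fwd2$emissions)
})

test_that("attention rows are stochastic and never attend to padding", {
  enc <- tiny_encoder(n_layers = 2, max_len = 8)
  b <- tokenize(c("a", "b", "c"), tiny_vocab(), 8)
  fwd <- encoder_forward(enc, b)
  for (l in seq_along(fwd$A)) {
    for (A in fwd$A[[l]]) {
      expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-5)
      expect_true(all(A[, 4:8] < 1e-8))  # padded keys receive no mass
    }
  }
})

test_that("emissions at real positions are invariant to extra padding", {
  cfg_small <- encoder_config(n_layers = 2, hidden_dim = 8, n_heads = 2,
                              ffn_dim = 16, vocab_size = 8, n_labels = 4,
                              max_len = 5, seed = 5)
  cfg_big <- cfg_small
  cfg_big$max_len <- 9L
  enc_s <- init_encoder(cfg_small)
  enc_b <- init_encoder(cfg_big)
  # share parameters: copy the small model's tables into the big one
  enc_b$par <- enc_s$par
  enc_b$par$pos_emb <- rbind(enc_s$par$pos_emb, matrix(0, 4, 8))
  v <- tiny_vocab()
  toks <- c("a", "b", "c")
  em_s <- encoder_forward(enc_s, tokenize(toks, v, 5))$emissions
  em_b <- encoder_forward(enc_b, tokenize(toks, v, 9))$emissions
  expect_equal(em_s[1:3, ], em_b[1:3, ], tolerance = 1e-5)
})

test_that("emission head produces one score per position and label", {
  enc <- tiny_encoder(n_labels = 5)
  b <- tokenize(c("a", "b"), tiny_vocab(), 6)
  fwd <- encoder_forward(enc, b)
  expect_equal(dim(fwd$emissions), c(6, 5))
  enc0 <- enc
  enc0$par$Wout[] <- 0; enc0$par$bout[] <- 0
  expect_true(all(encoder_forward(enc0, b)$emissions == 0))
  expect_error(encoder_config(n_layers = 1, hidden_dim = 8, n_heads = 2,
                              vocab_size = 8, n_labels = 1, max_len = 4),
               "labels")
})

test_that("softmax emission mode normalizes each position", {
  enc <- tiny_encoder(emissions_mode = "softmax")
  b <- tokenize(c("a", "b"), tiny_vocab(), 6)
  fwd <- encoder_forward(enc, b)
  expect_equal(rowSums(fwd$emissions), rep(1, 6), tolerance = 1e-8)
})

test_that("analytic gradients of encoder + CRF match finite differences", {
  enc <- tiny_encoder()
  tr <- init_transitions(4, "random", seed = 7)
  v <- tiny_vocab()
  b <- tokenize(c("a", "b", "c", "d"), v, 6)
  tags <- c(1L, 2L, 3L, 1L)
  lossfun <- function(par) {
    e2 <- enc; e2$par <- par
    fwd <- encoder_forward(e2, b)
    crf_nll(fwd$emissions[1:4, ], tr, tags)
  }
  fwd <- encoder_forward(enc, b, want_cache = TRUE)
  cg <- phideid:::crf_nll_grad(fwd$emissions[1:4, ], tr, tags)
  g_em <- matrix(0, 6, 4); g_em[1:4, ] <- cg$emissions
  g <- encoder_backward(enc, fwd, g_emissions = g_em)
  vec <- unlist(enc$par); gvec <- unlist(g)
  set.seed(1)
  idx <- sample(length(vec), 40)
  num <- vapply(idx, function(i) {
    e <- 1e-5
    v1 <- vec; v1[i] <- v1[i] + e
    v2 <- vec; v2[i] <- v2[i] - e
    (lossfun(utils::relist(v1, enc$par)) -
       lossfun(utils::relist(v2, enc$par))) / (2 * e)
  }, numeric(1))
  expect_equal(gvec[idx], num, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("the default student has fewer parameters than a 12-layer teacher", {
  # mirrors the published 67M (6-layer) vs 110M (12-layer) relationship,
  # asserted as an inequality at full width
  student <- encoder_config(n_layers = 6, hidden_dim = 768, n_heads = 12,
                            vocab_size = 100, n_labels = 9)
  teacher <- encoder_config(n_layers = 12, hidden_dim = 768, n_heads = 12,
                            vocab_size = 100, n_labels = 9)
  n_par <- function(cfg) {
    d <- cfg$hidden_dim; f <- cfg$ffn_dim
    per_layer <- 4 * (d * d + d) + d * f + f + f * d + d
    cfg$vocab_size * d + cfg$max_len * d + cfg$n_token_types * d +
      cfg$n_layers * per_layer + d * cfg$n_labels + cfg$n_labels
  }
  expect_lt(n_par(student), n_par(teacher))
  # and the counting helper agrees with the closed form at toy scale
  enc <- tiny_encoder()
  cfg <- enc$config
  expect_equal(count_params(enc), n_par(cfg))
})
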