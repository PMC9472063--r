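test_that("layer mapping pairs student layers with every k-th teacher layer", {
  m <- map_layers(2, 6)
  expect_equal(m$k, 3)
  expect_equal(m$pairs$student, c(0, 1, 2))
  expect_equal(m$pairs$teacher, c(0, 3, 6))
  ident <- map_layers(4, 4)
  expect_equal(ident$k, 1)
  expect_equal(ident$pairs$teacher, 0:4)
  expect_error(map_layers(4, 6), "divisible")
})

test_that("identical states with identity projections give zero tr/emb loss", {
  enc <- tiny_encoder(n_layers = 2)
  b <- tokenize(c("a", "b", "c"), tiny_vocab(), 6)
  fwd <- encoder_forward(enc, b, want_cache = TRUE)
  mapping <- map_layers(2, 2)
  rows <- 1:3
  expect_equal(transformer_loss(fwd, fwd, mapping, diag(8), rows), 0)
  expect_equal(embedding_loss(fwd$E[rows, ], fwd$E[rows, ], diag(8)), 0)
})

test_that("embedding loss follows the projected mean-squared-error contract", {
  # scalar cases: exact projection nulls the loss; unit offset gives 1
  expect_equal(embedding_loss(matrix(1), matrix(3), matrix(1 / 3)), 0)
  expect_equal(embedding_loss(matrix(1), matrix(2), matrix(1)), 1)
  expect_error(embedding_loss(matrix(1, 2, 2), matrix(1, 2, 3),
                              matrix(1, 3, 3)), "shape")
})

test_that("a one-layer perturbation contributes exactly its MSE terms", {
  enc <- tiny_encoder(n_layers = 2)
  b <- tokenize(c("a", "b", "c"), tiny_vocab(), 6)
  fwd <- encoder_forward(enc, b, want_cache = TRUE)
  rows <- 1:3
  delta <- 0.1
  fwd2 <- fwd
  fwd2$H[[2]] <- fwd$H[[2]] + delta
  got <- transformer_loss(fwd, fwd2, map_layers(2, 2), diag(8), rows)
  expect_equal(got, mean((matrix(delta, 3, 8))^2), tolerance = 1e-12)
})

test_that("prediction loss floors at the teacher entropy and is monotone", {
  set.seed(2)
  Z <- matrix(rnorm(12), 3, 4)
  P <- exp(Z) / rowSums(exp(Z))
  entropy <- -mean(rowSums(P * log(P)))
  expect_equal(prediction_loss(Z, Z), entropy, tolerance = 1e-10)
  # teacher nearly one-hot: reduces to hard-label cross-entropy
  Zh <- matrix(-30, 2, 3); Zh[cbind(1:2, c(2, 3))] <- 30
  Zs <- matrix(rnorm(6), 2, 3)
  logq <- Zs - apply(Zs, 1, function(z) log(sum(exp(z))))
  expect_equal(prediction_loss(Zh, Zs),
               -mean(logq[cbind(1:2, c(2, 3))]), tolerance = 1e-6)
  # moving student logits from uniform toward the teacher decreases the loss
  Zu <- matrix(0, 3, 4)
  losses <- vapply(seq(0, 1, by = 0.25), function(a) {
    prediction_loss(Z, (1 - a) * Zu + a * Z)
  }, numeric(1))
  expect_true(all(diff(losses) < 1e-12))
  expect_error(prediction_loss(Z, matrix(Inf, 3, 4)), "non-finite")
})

test_that("distillation losses sum exactly and respect their floors", {
  enc <- tiny_encoder(n_layers = 2, seed = 3)
  b <- tokenize(c("a", "b", "c", "d"), tiny_vocab(), 6)
  # self-distillation fixture: student == teacher, k = 1
  dl <- distill_losses(enc, enc, b)
  expect_equal(dl$L_tr, 0)
  expect_equal(dl$L_emb, 0)
  fwd <- encoder_forward(enc, b, want_cache = TRUE)
  P <- phideid:::row_softmax(fwd$cache$logits[1:4, ])
  expect_equal(dl$L_pr, -mean(rowSums(P * log(P))), tolerance = 1e-10)
  expect_equal(dl$L_total, dl$L_tr + dl$L_emb + dl$L_pr)
  # a different student: all losses at or above the floors, sum still exact
  st <- tiny_encoder(n_layers = 1, seed = 11)
  dl2 <- distill_losses(enc, st, b)
  expect_gte(dl2$L_tr, 0)
  expect_gte(dl2$L_emb, 0)
  expect_equal(dl2$L_total, dl2$L_tr + dl2$L_emb + dl2$L_pr)
})

test_that("distillation training reduces the total loss deterministically", {
  set.seed(404)
  co <- phi_corpus(replicate(30, random_sentence(len = sample(3:6, 1)),
                             simplify = FALSE))
  cfg_t <- encoder_config(n_layers = 4, hidden_dim = 8, n_heads = 2,
                          ffn_dim = 16, max_len = 8)
  teacher <- train_tagger(co, cfg_t,
                          tagger_train_config(epochs = 1, lr = 5e-3, seed = 2))
  cfg_s <- encoder_config(n_layers = 2, hidden_dim = 8, n_heads = 2,
                          ffn_dim = 16, max_len = 8)
  st <- distill(teacher, cfg_s, co, epochs = 4, seed = 5, lr = 5e-3)
  tr <- attr(st, "trace")
  expect_lt(tail(tr$L_total, 1), tr$L_total[1])
  expect_equal(tr$L_total, tr$L_tr + tr$L_emb + tr$L_pr, tolerance = 1e-12)
  expect_true(all(tr$L_tr >= 0) && all(tr$L_emb >= 0))
  st2 <- distill(teacher, cfg_s, co, epochs = 4, seed = 5, lr = 5e-3)
  expect_identical(attr(st, "trace"), attr(st2, "trace"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_loss_trace(tr, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(tr))
})

test_that("distillation gradients match finite differences", {
  teacher <- tiny_encoder(n_layers = 2, seed = 3)
  student <- tiny_encoder(n_layers = 1, seed = 9)
  b <- tokenize(c("a", "b", "c"), tiny_vocab(), 6)
  mapping <- map_layers(1, 2)
  W_h <- diag(8); W_e <- diag(8)
  t_fwd <- encoder_forward(teacher, b, want_cache = TRUE)
  lossfun <- function(par) {
    s2 <- student; s2$par <- par
    s_fwd <- encoder_forward(s2, b, want_cache = TRUE)
    dl <- phideid:::distill_losses_grads(teacher, s2, t_fwd, s_fwd, mapping,
                                         W_h, W_e, 1:3)
    dl$L_total
  }
  s_fwd <- encoder_forward(student, b, want_cache = TRUE)
  dl <- phideid:::distill_losses_grads(teacher, student, t_fwd, s_fwd,
                                       mapping, W_h, W_e, 1:3)
  g <- encoder_backward(student, s_fwd, g_emissions = dl$g_em, g_H = dl$g_H,
                        g_A = dl$g_A, g_E = dl$g_E)
  vec <- unlist(student$par); gvec <- unlist(g)
  set.seed(6)
  idx <- sample(length(vec), 30)
  num <- vapply(idx, function(i) {
    e <- 1e-5
    v1 <- vec; v1[i] <- v1[i] + e
    v2 <- vec; v2[i] <- v2[i] - e
    (lossfun(utils::relist(v1, student$par)) -
       lossfun(utils::relist(v2, student$par))) / (2 * e)
  }, numeric(1))
  expect_equal(gvec[idx], num, tolerance = 1e-4, ignore_attr = TRUE)
})
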