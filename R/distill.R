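# Transformer-layer knowledge distillation: an M-layer teacher transfers
# attention maps, hidden states, embedding output and emission logits to an
# N-layer student (M = k * N) through three summed losses
# (transformer-layer, embedding, prediction).

#' Teacher-to-student layer mapping
#'
#' Student layer `n` learns from teacher layer `k * n`, with `k = M / N`;
#' the embedding layers form the additional pair (0, 0).
#'
#' @param N Student transformer-layer count.
#' @param M Teacher transformer-layer count (must be a multiple of `N`).
#' @return List with `k` and `pairs` (`data.frame` student/teacher indices,
#'   embedding pair first).
#' @export
map_layers <- function(N, M) {
  if (N < 1 || M < N) stop("need 1 <= N <= M")
  if (M %% N != 0) stop(sprintf("M = %d is not divisible by N = %d", M, N))
  k <- M %/% N
  list(k = k,
       pairs = data.frame(student = c(0L, seq_len(N)),
                          teacher = c(0L, k * seq_len(N))))
}

mse <- function(a, b) mean((a - b)^2)

#' Transformer-layer loss
#'
#' Sum over mapped layers of the attention-map mean-squared error (averaged
#' over heads) plus the mean-squared error between the projected student
#' hidden state (`H_S W_h`) and the teacher hidden state. Computed over the
#' real (unpadded) positions.
#'
#' @param t_fwd,s_fwd Teacher and student [encoder_forward()] outputs.
#' @param mapping A [map_layers()] result.
#' @param W_h Student-to-teacher hidden projection (identity when widths
#'   match).
#' @param rows Integer vector of real positions.
#' @return Scalar loss.
#' @export
transformer_loss <- function(t_fwd, s_fwd, mapping, W_h, rows) {
  total <- 0
  layer_pairs <- mapping$pairs[mapping$pairs$student > 0, , drop = FALSE]
  for (r in seq_len(nrow(layer_pairs))) {
    sn <- layer_pairs$student[r]; tm <- layer_pairs$teacher[r]
    A_s <- s_fwd$A[[sn]]; A_t <- t_fwd$A[[tm]]
    if (length(A_s) != length(A_t)) stop("attention head count mismatch")
    attn <- mean(vapply(seq_along(A_s), function(hh) {
      mse(A_s[[hh]][rows, , drop = FALSE], A_t[[hh]][rows, , drop = FALSE])
    }, numeric(1)))
    hs <- s_fwd$H[[sn]][rows, , drop = FALSE] %*% W_h
    hid <- mse(hs, t_fwd$H[[tm]][rows, , drop = FALSE])
    total <- total + attn + hid
  }
  total
}

#' Embedding-layer loss
#'
#' Mean-squared error between the student embedding output and the projected
#' teacher embedding output, `MSE(E_S, E_T W_e)`.
#'
#' @param E_S,E_T Student and teacher embedding outputs (real rows only).
#' @param W_e Teacher-to-student embedding projection.
#' @return Scalar loss.
#' @export
embedding_loss <- function(E_S, E_T, W_e) {
  proj <- E_T %*% W_e
  if (!all(dim(proj) == dim(E_S))) stop("projected embedding shape mismatch")
  mse(E_S, proj)
}

#' Prediction loss
#'
#' Cross-entropy of the student emission logits against the teacher's
#' softened emission distribution, averaged over positions:
#' `-(1/L) sum_i softmax(Z_T[i,]) . log softmax(Z_S[i,] )`. Minimized (at
#' the teacher-entropy floor) when the student logits match the teacher's.
#'
#' @param Z_T,Z_S Teacher and student logit matrices (real rows only).
#' @param temperature Softmax temperature (default 1).
#' @return Scalar loss.
#' @export
prediction_loss <- function(Z_T, Z_S, temperature = 1) {
  if (!all(dim(Z_T) == dim(Z_S))) stop("logit shape mismatch")
  if (any(!is.finite(Z_T)) || any(!is.finite(Z_S))) stop("non-finite logits")
  P_t <- row_softmax(Z_T / temperature)
  logq <- Z_S / temperature
  logq <- logq - apply(logq, 1, function(z) logsumexp(z))
  -mean(rowSums(P_t * logq))
}

# all three losses plus gradients injected into the student backward pass
distill_losses_grads <- function(teacher, student, t_fwd, s_fwd, mapping,
                                 W_h, W_e, rows, temperature = 1) {
  cfgS <- student$config
  L <- cfgS$max_len
  n_rows <- length(rows)
  # prediction loss on emission logits
  Z_t <- t_fwd$cache$logits[rows, , drop = FALSE]
  Z_s <- s_fwd$cache$logits[rows, , drop = FALSE]
  L_pr <- prediction_loss(Z_t, Z_s, temperature)
  P_t <- row_softmax(Z_t / temperature)
  P_s <- row_softmax(Z_s / temperature)
  g_em <- matrix(0, L, cfgS$n_labels)
  g_em[rows, ] <- (P_s - P_t) / (n_rows * temperature)
  # embedding loss
  E_s <- s_fwd$E[rows, , drop = FALSE]
  E_t <- t_fwd$E[rows, , drop = FALSE]
  proj <- E_t %*% W_e
  L_emb <- mse(E_s, proj)
  diff_e <- 2 * (E_s - proj) / length(E_s)
  g_E <- matrix(0, L, cfgS$hidden_dim)
  g_E[rows, ] <- diff_e
  g_We <- -t(E_t) %*% diff_e
  # transformer-layer loss
  layer_pairs <- mapping$pairs[mapping$pairs$student > 0, , drop = FALSE]
  g_H <- vector("list", cfgS$n_layers)
  g_A <- vector("list", cfgS$n_layers)
  g_Wh <- matrix(0, nrow(W_h), ncol(W_h))
  L_tr <- 0
  h <- cfgS$n_heads
  for (r in seq_len(nrow(layer_pairs))) {
    sn <- layer_pairs$student[r]; tm <- layer_pairs$teacher[r]
    A_s <- s_fwd$A[[sn]]; A_t <- t_fwd$A[[tm]]
    if (length(A_s) != length(A_t)) stop("attention head count mismatch")
    g_A[[sn]] <- vector("list", h)
    attn_terms <- numeric(h)
    for (hh in seq_len(h)) {
      da <- A_s[[hh]][rows, , drop = FALSE] - A_t[[hh]][rows, , drop = FALSE]
      attn_terms[hh] <- mean(da^2)
      gfull <- matrix(0, L, L)
      gfull[rows, ] <- 2 * da / (h * length(da))
      g_A[[sn]][[hh]] <- gfull
    }
    Hs <- s_fwd$H[[sn]][rows, , drop = FALSE]
    hs_proj <- Hs %*% W_h
    dh <- hs_proj - t_fwd$H[[tm]][rows, , drop = FALSE]
    hid <- mean(dh^2)
    L_tr <- L_tr + mean(attn_terms) + hid
    gh <- matrix(0, L, cfgS$hidden_dim)
    gh[rows, ] <- (2 * dh / length(dh)) %*% t(W_h)
    g_H[[sn]] <- gh
    g_Wh <- g_Wh + t(Hs) %*% (2 * dh / length(dh))
  }
  list(L_tr = L_tr, L_emb = L_emb, L_pr = L_pr,
       L_total = L_tr + L_emb + L_pr,
       g_em = g_em, g_E = g_E, g_H = g_H, g_A = g_A,
       g_Wh = g_Wh, g_We = g_We)
}

#' Compute the distillation losses for one sentence (no training)
#'
#' @param teacher,student `phi_encoder` objects (teacher layer count a
#'   multiple of the student's).
#' @param batch A [tokenize()] batch.
#' @param W_h,W_e Projection matrices (identity defaults when widths match).
#' @param temperature Prediction-loss temperature.
#' @return List `L_tr`, `L_emb`, `L_pr`, `L_total`.
#' @export
distill_losses <- function(teacher, student, batch, W_h = NULL, W_e = NULL,
                           temperature = 1) {
  mapping <- map_layers(student$config$n_layers, teacher$config$n_layers)
  if (is.null(W_h)) W_h <- diag(student$config$hidden_dim)
  if (is.null(W_e)) W_e <- diag(teacher$config$hidden_dim)
  t_fwd <- encoder_forward(teacher, batch, want_cache = TRUE)
  s_fwd <- encoder_forward(student, batch, want_cache = TRUE)
  rows <- seq_len(batch$length)
  out <- distill_losses_grads(teacher, student, t_fwd, s_fwd, mapping,
                              W_h, W_e, rows, temperature)
  out[c("L_tr", "L_emb", "L_pr", "L_total")]
}

#' Distill a teacher encoder into a compact student
#'
#' Trains a freshly initialized N-layer student (plus the hidden and
#' embedding projections when widths differ) to minimize the summed
#' distillation loss over the corpus stream with Adam. The teacher is
#' frozen.
#'
#' @param teacher A trained `phi_tagger` (its encoder is the teacher).
#' @param student_config [encoder_config()] for the student;
#'   `vocab_size`/`n_labels`/`max_len` are forced to the teacher's.
#' @param corpus Training `phi_corpus` (tokenized with the teacher vocab).
#' @param epochs Passes over the corpus.
#' @param seed Seed for student init and data order.
#' @param lr Adam learning rate.
#' @param batch_size Sentences per update.
#' @param temperature Prediction-loss temperature.
#' @param length_one Distill on length-1 sub-sequences (single tokens)
#'   instead of whole sentences.
#' @return A `phi_tagger` whose encoder is the distilled student and whose
#'   transition matrix is inherited from the teacher, with attribute
#'   `"trace"`: `data.frame(step, L_tr, L_emb, L_pr, L_total)`.
#' @export
distill <- function(teacher, student_config, corpus, epochs = 3L, seed = 1L,
                    lr = 2e-3, batch_size = 8L, temperature = 1,
                    length_one = FALSE) {
  t_enc <- teacher$encoder
  student_config$vocab_size <- t_enc$config$vocab_size
  student_config$n_labels <- t_enc$config$n_labels
  student_config$max_len <- t_enc$config$max_len
  student_config$n_heads <- t_enc$config$n_heads
  student_config$seed <- as.integer(seed)
  mapping <- map_layers(student_config$n_layers, t_enc$config$n_layers)
  student <- init_encoder(student_config)
  same_width <- student_config$hidden_dim == t_enc$config$hidden_dim
  params <- list(enc = student$par,
                 W_h = if (same_width) diag(student_config$hidden_dim) else
                   with_seed(seed + 1L, rnorm_mat(student_config$hidden_dim,
                                                  t_enc$config$hidden_dim, 0.1)),
                 W_e = if (same_width) diag(t_enc$config$hidden_dim) else
                   with_seed(seed + 2L, rnorm_mat(t_enc$config$hidden_dim,
                                                  student_config$hidden_dim, 0.1)))
  opt <- adam_init(params)
  batches <- lapply(corpus$sentences, function(s) {
    tokenize(s$tokens, teacher$token_vocab, t_enc$config$max_len)
  })
  if (length_one) {
    batches <- unlist(lapply(batches, function(b) {
      lapply(seq_len(b$length), function(i) {
        tokenize(teacher$token_vocab[b$ids[i]], teacher$token_vocab,
                 t_enc$config$max_len)
      })
    }), recursive = FALSE)
  }
  trace <- data.frame(step = integer(), L_tr = numeric(), L_emb = numeric(),
                      L_pr = numeric(), L_total = numeric())
  n <- length(batches)
  step <- 0L
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      order_idx <- sample.int(n)
      i <- 1L
      while (i <= n) {
        take <- order_idx[i:min(i + batch_size - 1L, n)]
        g_acc <- NULL
        loss_acc <- c(L_tr = 0, L_emb = 0, L_pr = 0, L_total = 0)
        for (j in take) {
          b <- batches[[j]]
          t_fwd <- encoder_forward(t_enc, b, want_cache = TRUE)
          student$par <- params$enc
          s_fwd <- encoder_forward(student, b, want_cache = TRUE)
          dl <- distill_losses_grads(t_enc, student, t_fwd, s_fwd, mapping,
                                     params$W_h, params$W_e,
                                     seq_len(b$length), temperature)
          if (!is.finite(dl$L_total)) stop("distillation diverged (non-finite loss)")
          g_enc <- encoder_backward(student, s_fwd, g_emissions = dl$g_em,
                                    g_H = dl$g_H, g_A = dl$g_A, g_E = dl$g_E)
          g <- list(enc = g_enc, W_h = dl$g_Wh, W_e = dl$g_We)
          g_acc <- if (is.null(g_acc)) g else add_params(g_acc, g)
          loss_acc <- loss_acc + c(dl$L_tr, dl$L_emb, dl$L_pr, dl$L_total)
        }
        g_acc <- scale_params(g_acc, 1 / length(take))
        upd <- adam_step(params, g_acc, opt, lr = lr)
        params <- upd$par; opt <- upd$state
        step <- step + 1L
        la <- loss_acc / length(take)
        trace <- rbind(trace, data.frame(step = step, L_tr = la[1],
                                         L_emb = la[2], L_pr = la[3],
                                         L_total = la[4]))
        i <- i + batch_size
      }
    }
  })
  student$par <- params$enc
  model <- new_tagger(student, teacher$transitions, teacher$token_vocab,
                      teacher$label_vocab, teacher$categories)
  attr(model, "trace") <- trace
  attr(model, "projections") <- list(W_h = params$W_h, W_e = params$W_e)
  model
}

#' Write a distillation loss trace as CSV
#'
#' @param trace The `"trace"` attribute of a [distill()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
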