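# Multi-layer self-attention encoder producing per-token features, per-layer
# attention maps / hidden states, and CRF emission scores.
#
# The forward pass caches every intermediate needed by the analytic backward
# pass; the backward pass additionally accepts gradients injected at the
# per-layer hidden states, attention maps, and the embedding output, which is
# what transformer-layer distillation needs.

ATTN_MASK_SCORE <- -1e9

#' Encoder configuration
#'
#' @param n_layers Number of self-attention blocks (student default 6).
#' @param hidden_dim Feature width (default 768); must be divisible by
#'   `n_heads`.
#' @param n_heads Attention head count (default 12).
#' @param ffn_dim Feed-forward inner width (default `4 * hidden_dim`).
#' @param vocab_size Token vocabulary size (including `<pad>`, `<unk>`).
#' @param n_labels Emission width = tag vocabulary size.
#' @param n_token_types Token-type vocabulary size (default 1).
#' @param max_len Fixed sequence length after padding/truncation
#'   (default 128).
#' @param dropout Dropout rate applied after each sublayer during training
#'   (default 0).
#' @param emissions_mode `"logits"` (default) passes raw scores to the CRF;
#'   `"softmax"` normalizes each position first.
#' @param seed Seed for parameter initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 6L, hidden_dim = 768L, n_heads = 12L,
                           ffn_dim = 4L * hidden_dim, vocab_size = NA,
                           n_labels = NA, n_token_types = 1L, max_len = 128L,
                           dropout = 0, emissions_mode = c("logits", "softmax"),
                           seed = 1L) {
  emissions_mode <- match.arg(emissions_mode)
  if (hidden_dim %% n_heads != 0) stop("hidden_dim must be divisible by n_heads")
  if (max_len < 1) stop("max_len must be >= 1")
  if (!is.na(n_labels) && n_labels < 2) stop("need at least 2 labels")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 vocab_size = as.integer(vocab_size),
                 n_labels = as.integer(n_labels),
                 n_token_types = as.integer(n_token_types),
                 max_len = as.integer(max_len),
                 dropout = dropout,
                 emissions_mode = emissions_mode,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

rnorm_mat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

#' Initialize encoder parameters
#'
#' Weights are drawn N(0, 0.02^2) (the convention of the BERT family);
#' biases start at zero. Position embeddings are learned.
#'
#' @param config An [encoder_config()].
#' @return A `phi_encoder` object (config + parameter list).
#' @export
init_encoder <- function(config) {
  if (is.na(config$vocab_size) || is.na(config$n_labels)) {
    stop("vocab_size and n_labels must be set before initialization")
  }
  if (config$n_labels < 2) stop("need at least 2 labels")
  d <- config$hidden_dim; f <- config$ffn_dim
  par <- with_seed(config$seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = rnorm_mat(d, d), bq = numeric(d),
           Wk = rnorm_mat(d, d), bk = numeric(d),
           Wv = rnorm_mat(d, d), bv = numeric(d),
           Wo = rnorm_mat(d, d), bo = numeric(d),
           W1 = rnorm_mat(d, f), b1 = numeric(f),
           W2 = rnorm_mat(f, d), b2 = numeric(d))
    })
    list(tok_emb = rnorm_mat(config$vocab_size, d),
         pos_emb = rnorm_mat(config$max_len, d),
         type_emb = rnorm_mat(config$n_token_types, d),
         layers = layers,
         Wout = rnorm_mat(d, config$n_labels),
         bout = numeric(config$n_labels))
  })
  structure(list(config = config, par = par), class = "phi_encoder")
}

#' @export
print.phi_encoder <- function(x, ...) {
  cat(sprintf("<phi_encoder> %d layers, width %d, %d heads, %s parameters\n",
              x$config$n_layers, x$config$hidden_dim, x$config$n_heads,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param encoder A `phi_encoder`.
#' @return Integer-valued numeric count over all weight matrices and biases.
#' @export
count_params <- function(encoder) {
  sum(unlist(rapply(encoder$par, length, how = "unlist")))
}

#' Convert a token sequence to fixed-length id form
#'
#' Pads with `<pad>` up to `max_len` and truncates beyond it; unknown
#' surface units map to `<unk>`. The original (possibly truncated) length is
#' recorded so downstream tag sequences can be truncated consistently.
#'
#' @param tokens Character vector of surface units (non-empty).
#' @param token_vocab Token vocabulary with `<pad>`, `<unk>` reserved.
#' @param max_len Fixed output length.
#' @return List with `ids`, `type_ids`, `mask` (1 real / 0 pad), `length`,
#'   `truncated`.
#' @export
tokenize <- function(tokens, token_vocab, max_len) {
  if (length(tokens) == 0) stop("empty sentence")
  if (!identical(token_vocab[1:2], c(PAD_TOKEN, UNK_TOKEN))) {
    stop("token_vocab must reserve <pad>, <unk> at indices 1, 2")
  }
  truncated <- length(tokens) > max_len
  kept <- utils::head(tokens, max_len)
  ids <- match(kept, token_vocab)
  ids[is.na(ids)] <- 2L   # <unk>
  n <- length(kept)
  ids <- c(ids, rep(1L, max_len - n))          # <pad>
  mask <- c(rep(1L, n), rep(0L, max_len - n))
  list(ids = as.integer(ids), type_ids = rep(1L, max_len),
       mask = mask, length = n, truncated = truncated)
}

row_softmax <- function(m) {
  mx <- apply(m, 1, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

#' Encoder forward pass
#'
#' Computes the summed word/position/token-type embedding, runs the
#' self-attention blocks (attention masked so padded positions are never
#' attended to), and projects the final features to emission scores.
#'
#' @param encoder A `phi_encoder`.
#' @param batch Output of [tokenize()].
#' @param want_cache Keep intermediates for [encoder_backward()].
#' @param training Apply dropout (uses the current RNG stream).
#' @return List with `E` (embedding output), `H` (per-layer hidden states),
#'   `A` (per-layer, per-head attention maps), `features` (final hidden
#'   state; equals `E` when `n_layers = 0`), `emissions`
#'   (`max_len x n_labels`), and `cache` when requested.
#' @export
encoder_forward <- function(encoder, batch, want_cache = FALSE,
                            training = FALSE) {
  cfg <- encoder$config; par <- encoder$par
  d <- cfg$hidden_dim; h <- cfg$n_heads; dk <- d %/% h
  L <- cfg$max_len
  if (length(batch$ids) != L) stop("batch length does not match max_len")
  if (any(batch$ids < 1 | batch$ids > cfg$vocab_size)) stop("token id out of range")
  E <- par$tok_emb[batch$ids, , drop = FALSE] +
    par$pos_emb +
    par$type_emb[batch$type_ids, , drop = FALSE]
  X <- E
  Hs <- vector("list", cfg$n_layers)
  As <- vector("list", cfg$n_layers)
  caches <- if (want_cache) vector("list", cfg$n_layers) else NULL
  key_mask <- batch$mask == 0L
  drop_p <- if (training) cfg$dropout else 0
  for (l in seq_len(cfg$n_layers)) {
    lp <- par$layers[[l]]
    Q <- X %*% lp$Wq; Q <- sweep(Q, 2, lp$bq, "+")
    K <- X %*% lp$Wk; K <- sweep(K, 2, lp$bk, "+")
    V <- X %*% lp$Wv; V <- sweep(V, 2, lp$bv, "+")
    A_heads <- vector("list", h)
    O <- matrix(0, L, d)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
      if (any(key_mask)) S[, key_mask] <- ATTN_MASK_SCORE
      A <- row_softmax(S)
      A_heads[[hh]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    attn_out <- sweep(O %*% lp$Wo, 2, lp$bo, "+")
    dmask_a <- NULL
    if (drop_p > 0) {
      dmask_a <- matrix(stats::rbinom(L * d, 1L, 1 - drop_p), L, d) / (1 - drop_p)
      attn_out <- attn_out * dmask_a
    }
    X1 <- X + attn_out
    Z1 <- sweep(X1 %*% lp$W1, 2, lp$b1, "+")
    Hff <- pmax(Z1, 0)
    ffn_out <- sweep(Hff %*% lp$W2, 2, lp$b2, "+")
    dmask_f <- NULL
    if (drop_p > 0) {
      dmask_f <- matrix(stats::rbinom(L * d, 1L, 1 - drop_p), L, d) / (1 - drop_p)
      ffn_out <- ffn_out * dmask_f
    }
    X2 <- X1 + ffn_out
    Hs[[l]] <- X2
    As[[l]] <- A_heads
    if (want_cache) {
      caches[[l]] <- list(X_in = X, Q = Q, K = K, V = V, A = A_heads, O = O,
                          X1 = X1, Hff = Hff, dmask_a = dmask_a,
                          dmask_f = dmask_f)
    }
    X <- X2
  }
  logits <- sweep(X %*% par$Wout, 2, par$bout, "+")
  emissions <- if (cfg$emissions_mode == "softmax") row_softmax(logits) else logits
  out <- list(E = E, H = Hs, A = As, features = X, emissions = emissions)
  if (want_cache) {
    out$cache <- list(layers = caches, E = E, X_last = X, batch = batch,
                      logits = logits)
  }
  out
}

# Gradient of a row-softmax output wrt its input, applied to upstream grad g.
softmax_backward <- function(A, g) {
  A * (g - rowSums(g * A))
}

#' Encoder backward pass
#'
#' Backpropagates a gradient on the emission matrix (plus optional gradients
#' injected at per-layer hidden states `g_H`, per-layer per-head attention
#' maps `g_A`, and the embedding output `g_E`) to gradients over every
#' encoder parameter.
#'
#' @param encoder A `phi_encoder`.
#' @param fwd Output of [encoder_forward()] with `want_cache = TRUE`.
#' @param g_emissions Gradient wrt the emission matrix (or `NULL`).
#' @param g_H Optional list (per layer) of hidden-state gradients.
#' @param g_A Optional list (per layer) of per-head attention-map gradients.
#' @param g_E Optional gradient wrt the embedding output.
#' @return Gradient list with the same structure as the parameter list.
#' @export
encoder_backward <- function(encoder, fwd, g_emissions = NULL, g_H = NULL,
                             g_A = NULL, g_E = NULL) {
  cfg <- encoder$config; par <- encoder$par
  d <- cfg$hidden_dim; h <- cfg$n_heads; dk <- d %/% h
  L <- cfg$max_len
  cache <- fwd$cache
  if (is.null(cache)) stop("forward pass must be run with want_cache = TRUE")
  grads <- list(tok_emb = matrix(0, cfg$vocab_size, d),
                pos_emb = matrix(0, L, d),
                type_emb = matrix(0, cfg$n_token_types, d),
                layers = vector("list", cfg$n_layers),
                Wout = matrix(0, d, cfg$n_labels),
                bout = numeric(cfg$n_labels))
  gX <- matrix(0, L, d)
  if (!is.null(g_emissions)) {
    g_logits <- if (cfg$emissions_mode == "softmax") {
      softmax_backward(fwd$emissions, g_emissions)
    } else g_emissions
    grads$Wout <- t(cache$X_last) %*% g_logits
    grads$bout <- colSums(g_logits)
    gX <- g_logits %*% t(par$Wout)
  }
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- par$layers[[l]]
    lc <- cache$layers[[l]]
    if (!is.null(g_H) && !is.null(g_H[[l]])) gX <- gX + g_H[[l]]
    # FFN sublayer: X2 = X1 + drop(ffn(X1))
    g_ffn_out <- gX
    if (!is.null(lc$dmask_f)) g_ffn_out <- g_ffn_out * lc$dmask_f
    gW2 <- t(lc$Hff) %*% g_ffn_out
    gb2 <- colSums(g_ffn_out)
    gHff <- g_ffn_out %*% t(lp$W2)
    gZ1 <- gHff * (lc$Hff > 0)
    gW1 <- t(lc$X1) %*% gZ1
    gb1 <- colSums(gZ1)
    gX1 <- gX + gZ1 %*% t(lp$W1)
    # attention sublayer: X1 = X + drop(O Wo + bo)
    g_attn_out <- gX1
    if (!is.null(lc$dmask_a)) g_attn_out <- g_attn_out * lc$dmask_a
    gWo <- t(lc$O) %*% g_attn_out
    gbo <- colSums(g_attn_out)
    gO <- g_attn_out %*% t(lp$Wo)
    gQ <- matrix(0, L, d); gK <- matrix(0, L, d); gV <- matrix(0, L, d)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      A <- lc$A[[hh]]
      gA <- gO[, cols, drop = FALSE] %*% t(lc$V[, cols, drop = FALSE])
      if (!is.null(g_A) && !is.null(g_A[[l]]) && !is.null(g_A[[l]][[hh]])) {
        gA <- gA + g_A[[l]][[hh]]
      }
      gV[, cols] <- t(A) %*% gO[, cols, drop = FALSE]
      gS <- softmax_backward(A, gA)
      gQ[, cols] <- gS %*% lc$K[, cols, drop = FALSE] / sqrt(dk)
      gK[, cols] <- t(gS) %*% lc$Q[, cols, drop = FALSE] / sqrt(dk)
    }
    gWq <- t(lc$X_in) %*% gQ; gbq <- colSums(gQ)
    gWk <- t(lc$X_in) %*% gK; gbk <- colSums(gK)
    gWv <- t(lc$X_in) %*% gV; gbv <- colSums(gV)
    gX <- gX1 + gQ %*% t(lp$Wq) + gK %*% t(lp$Wk) + gV %*% t(lp$Wv)
    grads$layers[[l]] <- list(Wq = gWq, bq = gbq, Wk = gWk, bk = gbk,
                              Wv = gWv, bv = gbv, Wo = gWo, bo = gbo,
                              W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  if (!is.null(g_E)) gX <- gX + g_E
  ids <- cache$batch$ids
  grads$tok_emb <- rowsum_into(gX, ids, cfg$vocab_size)
  grads$pos_emb <- gX
  grads$type_emb <- rowsum_into(gX, cache$batch$type_ids, cfg$n_token_types)
  grads
}

rowsum_into <- function(g, ids, n_rows) {
  out <- matrix(0, n_rows, ncol(g))
  agg <- rowsum(g, group = ids)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Emission scores for a sentence
#'
#' Convenience wrapper: tokenize, run the encoder, and return the emission
#' rows for the real (unpadded) positions.
#'
#' @param encoder A `phi_encoder`.
#' @param tokens Character vector of surface units.
#' @param token_vocab Token vocabulary.
#' @return `length(tokens) x n_labels` emission matrix (truncated to
#'   `max_len` rows if the sentence is longer).
#' @export
emissions <- function(encoder, tokens, token_vocab) {
  batch <- tokenize(tokens, token_vocab, encoder$config$max_len)
  fwd <- encoder_forward(encoder, batch)
  fwd$emissions[seq_len(batch$length), , drop = FALSE]
}
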