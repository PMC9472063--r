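# Independent oracles and fixture builders shared by the suite.

# Brute-force log-partition: enumerate all K^L paths, score by direct
# summation, log-sum-exp the scores. Independent of the forward recursion.
brute_logZ <- function(em, tr) {
  K <- ncol(em); L <- nrow(em); st <- K + 1L; en <- K + 2L
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  sc <- apply(paths, 1, function(p) {
    s <- sum(em[cbind(seq_len(L), p)]) + tr[st, p[1]] + tr[p[L], en]
    if (L > 1) s <- s + sum(tr[cbind(p[-L], p[-1])])
    s
  })
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

# Brute-force Viterbi: exhaustive argmax with lowest-lexicographic tie-break
# (expand.grid enumerates with the first variable fastest, so the first
# maximum is the lexicographically smallest path read left-to-right).
brute_viterbi <- function(em, tr) {
  K <- ncol(em); L <- nrow(em); st <- K + 1L; en <- K + 2L
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  sc <- apply(paths, 1, function(p) {
    s <- sum(em[cbind(seq_len(L), p)]) + tr[st, p[1]] + tr[p[L], en]
    if (L > 1) s <- s + sum(tr[cbind(p[-L], p[-1])])
    s
  })
  best <- which.max(sc)
  list(tags = unname(paths[best, ]), score = sc[best])
}

brute_all_scores <- function(em, tr) {
  K <- ncol(em); L <- nrow(em); st <- K + 1L; en <- K + 2L
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  apply(paths, 1, function(p) {
    s <- sum(em[cbind(seq_len(L), p)]) + tr[st, p[1]] + tr[p[L], en]
    if (L > 1) s <- s + sum(tr[cbind(p[-L], p[-1])])
    s
  })
}

# Independent entity-level scorer: extracts spans by scanning B- anchors and
# compares span sets per sentence as strings. Written apart from the package
# implementation on purpose.
indep_entity_f1 <- function(gold_tags_list, pred_tags_list) {
  span_keys <- function(tags) {
    keys <- character(0)
    i <- 1L
    while (i <= length(tags)) {
      if (grepl("^B-", tags[i])) {
        cat_i <- sub("^B-", "", tags[i])
        j <- i + 1L
        while (j <= length(tags) && tags[j] == paste0("I-", cat_i)) j <- j + 1L
        keys <- c(keys, paste(i, j - 1L, cat_i, sep = "_"))
        i <- j
      } else i <- i + 1L
    }
    keys
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (s in seq_along(gold_tags_list)) {
    g <- span_keys(gold_tags_list[[s]])
    p <- span_keys(pred_tags_list[[s]])
    tp <- tp + sum(p %in% g)
    fp <- fp + sum(!(p %in% g))
    fn <- fn + sum(!(g %in% p))
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
    tp = tp, fp = fp, fn = fn)
}

# Small random valid sentence (tokens + tags), for round-trip properties.
random_sentence <- function(len = sample(3:12, 1),
                            cats = phi_categories()) {
  tokens <- sprintf("t%02d", sample.int(30, len, replace = TRUE))
  tags <- rep("O", len)
  i <- 1L
  while (i <= len) {
    if (runif(1) < 0.3) {
      cat_i <- sample(cats, 1)
      span_len <- min(sample(1:3, 1), len - i + 1L)
      tags[i] <- paste0("B-", cat_i)
      if (span_len > 1) tags[(i + 1L):(i + span_len - 1L)] <- paste0("I-", cat_i)
      i <- i + span_len
    } else i <- i + 1L
  }
  labeled_sentence(tokens, tags)
}

# Tiny tokenizer fixture vocabulary.
tiny_vocab <- function(extra = letters[1:6]) c("<pad>", "<unk>", extra)

# Small encoder fixture shared by encoder/distillation tests.
tiny_encoder <- function(n_layers = 2, hidden_dim = 8, n_heads = 2,
                         vocab_size = 10, n_labels = 4, max_len = 6,
                         seed = 5, ...) {
  init_encoder(encoder_config(n_layers = n_layers, hidden_dim = hidden_dim,
                              n_heads = n_heads, ffn_dim = 2 * hidden_dim,
                              vocab_size = vocab_size, n_labels = n_labels,
                              max_len = max_len, seed = seed, ...))
}
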