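# Joint tagger: encoder emissions + CRF head, trained end-to-end by
# minimizing the CRF negative log-likelihood.

#' Training configuration for the tagger
#'
#' @param epochs Passes over the training corpus.
#' @param batch_size Sentences per parameter update.
#' @param lr Adam learning rate.
#' @param seed Global seed for initialization and data order.
#' @param constrain_train Apply the BIO transition mask during training as
#'   well as at decode time (default decode-time only).
#' @return A `tagger_train_config` list.
#' @export
tagger_train_config <- function(epochs = 5L, batch_size = 8L, lr = 2e-3,
                                seed = 1L, constrain_train = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed),
                 constrain_train = isTRUE(constrain_train)),
            class = "tagger_train_config")
}

model_fingerprint <- function(encoder_cfg, token_vocab, label_vocab) {
  paste(encoder_cfg$n_layers, encoder_cfg$hidden_dim, encoder_cfg$n_heads,
        encoder_cfg$max_len, length(token_vocab), length(label_vocab),
        paste(utils::head(token_vocab, 5), collapse = "|"),
        paste(label_vocab, collapse = "|"), sep = ":")
}

new_tagger <- function(encoder, transitions, token_vocab, label_vocab,
                       categories) {
  structure(list(encoder = encoder, transitions = transitions,
                 token_vocab = token_vocab, label_vocab = label_vocab,
                 categories = categories,
                 fingerprint = model_fingerprint(encoder$config, token_vocab,
                                                label_vocab)),
            class = "phi_tagger")
}

#' @export
print.phi_tagger <- function(x, ...) {
  cat(sprintf("<phi_tagger> %d-layer encoder (width %d), %d labels, %d token vocab\n",
              x$encoder$config$n_layers, x$encoder$config$hidden_dim,
              length(x$label_vocab), length(x$token_vocab)))
  invisible(x)
}

# NLL and gradients for one sentence. Returns NULL-safe gradient pieces for
# the encoder parameters and the transition matrix.
sentence_loss_grad <- function(encoder, transitions, batch, tag_ids,
                               constraint = NULL, training = FALSE) {
  fwd <- encoder_forward(encoder, batch, want_cache = TRUE, training = training)
  n <- batch$length
  em <- fwd$emissions[seq_len(n), , drop = FALSE]
  tr <- transitions
  if (!is.null(constraint)) tr[!constraint] <- tr[!constraint] + MASK_PENALTY
  cg <- crf_nll_grad(em, tr, tag_ids)
  g_em_full <- matrix(0, encoder$config$max_len, encoder$config$n_labels)
  g_em_full[seq_len(n), ] <- cg$emissions
  g_enc <- encoder_backward(encoder, fwd, g_emissions = g_em_full)
  list(nll = cg$nll, g_enc = g_enc, g_tr = cg$transitions)
}

#' Train the tagger end-to-end
#'
#' Minimizes the mean CRF negative log-likelihood over the training corpus
#' with Adam. When an evaluation corpus is supplied, entity-level micro-F1
#' is computed each epoch and the best-on-eval parameters are returned.
#'
#' @param train Training `phi_corpus` (vocabularies are taken from it).
#' @param config An [encoder_config()]; its `vocab_size`/`n_labels` are
#'   overridden to match the corpus.
#' @param train_config A [tagger_train_config()].
#' @param eval Optional evaluation `phi_corpus`.
#' @param quiet Suppress per-epoch messages.
#' @return A `phi_tagger` with attribute `"trace"`: a `data.frame` of
#'   per-epoch mean train NLL and (if available) eval micro-F1.
#' @export
train_tagger <- function(train, config, train_config = tagger_train_config(),
                         eval = NULL, quiet = TRUE) {
  label_vocab <- train$label_vocab
  token_vocab <- train$token_vocab
  config$vocab_size <- length(token_vocab)
  config$n_labels <- length(label_vocab)
  config$seed <- train_config$seed
  encoder <- init_encoder(config)
  transitions <- init_transitions(config$n_labels, init = "zero")
  constraint <- if (train_config$constrain_train) {
    bio_constraint_mask(label_vocab)
  } else NULL
  params <- list(enc = encoder$par, tr = transitions)
  opt <- adam_init(params)
  n <- length(train$sentences)
  batches <- prepare_batches(train, token_vocab, label_vocab, config$max_len)
  trace <- data.frame(epoch = integer(), train_nll = numeric(),
                      eval_f1 = numeric())
  best_f1 <- -Inf; best_params <- params
  with_seed(train_config$seed, {
    for (epoch in seq_len(train_config$epochs)) {
      order_idx <- sample.int(n)
      total_nll <- 0
      i <- 1L
      while (i <= n) {
        take <- order_idx[i:min(i + train_config$batch_size - 1L, n)]
        g_acc <- NULL
        for (j in take) {
          encoder$par <- params$enc
          sl <- sentence_loss_grad(encoder, params$tr, batches[[j]]$batch,
                                   batches[[j]]$tag_ids, constraint = constraint,
                                   training = config$dropout > 0)
          total_nll <- total_nll + sl$nll
          g <- list(enc = sl$g_enc, tr = sl$g_tr)
          g_acc <- if (is.null(g_acc)) g else add_params(g_acc, g)
        }
        g_acc <- scale_params(g_acc, 1 / length(take))
        upd <- adam_step(params, g_acc, opt, lr = train_config$lr)
        params <- upd$par; opt <- upd$state
        i <- i + train_config$batch_size
      }
      mean_nll <- total_nll / n
      f1 <- NA_real_
      if (!is.null(eval)) {
        encoder$par <- params$enc
        model_now <- new_tagger(encoder, params$tr, token_vocab, label_vocab,
                                train$categories)
        pred <- predict_corpus(model_now, eval)
        f1 <- score_entities(match_entities(eval, pred))$micro["f1"]
        if (f1 >= best_f1) { best_f1 <- f1; best_params <- params }
      } else {
        best_params <- params
      }
      trace <- rbind(trace, data.frame(epoch = epoch, train_nll = mean_nll,
                                       eval_f1 = unname(f1)))
      if (!quiet) {
        message(sprintf("epoch %d: train NLL %.4f eval F1 %s", epoch, mean_nll,
                        ifelse(is.na(f1), "-", sprintf("%.2f", f1))))
      }
    }
  })
  encoder$par <- best_params$enc
  model <- new_tagger(encoder, best_params$tr, token_vocab, label_vocab,
                      train$categories)
  attr(model, "trace") <- trace
  model
}

prepare_batches <- function(corpus, token_vocab, label_vocab, max_len) {
  lapply(corpus$sentences, function(s) {
    batch <- tokenize(s$tokens, token_vocab, max_len)
    tags <- utils::head(s$tags, batch$length)
    tag_ids <- match(tags, label_vocab)
    if (anyNA(tag_ids)) stop("sentence tag outside label vocabulary")
    list(batch = batch, tag_ids = tag_ids)
  })
}

#' Predict BIO tags with constrained Viterbi decoding
#'
#' @param model A `phi_tagger`.
#' @param newdata A `phi_corpus` or a list of character token vectors.
#' @return A `phi_corpus` of the same sentences with predicted tags; every
#'   output sequence satisfies the BIO validity rules.
#' @export
predict_corpus <- function(model, newdata) {
  token_lists <- if (inherits(newdata, "phi_corpus")) {
    lapply(newdata$sentences, `[[`, "tokens")
  } else newdata
  mask <- bio_constraint_mask(model$label_vocab)
  sentences <- lapply(token_lists, function(tokens) {
    em <- emissions(model$encoder, tokens, model$token_vocab)
    vit <- viterbi(em, model$transitions, mask = mask)
    tags <- model$label_vocab[vit$tags]
    if (length(tokens) > length(tags)) {
      # truncated tail gets O: predictions only exist up to max_len
      tags <- c(tags, rep("O", length(tokens) - length(tags)))
    }
    labeled_sentence(tokens, tags, source = "prediction")
  })
  phi_corpus(sentences, categories = model$categories,
             token_vocab = model$token_vocab)
}

#' Normalized path probability of the decoded tagging
#'
#' `exp(viterbi score - log partition)`, in (0, 1]; used as the confidence
#' measure for annotation bootstrapping.
#'
#' @param model A `phi_tagger`.
#' @param tokens Character token vector.
#' @return Scalar confidence.
#' @export
path_confidence <- function(model, tokens) {
  em <- emissions(model$encoder, tokens, model$token_vocab)
  vit <- viterbi(em, model$transitions, mask = NULL)
  exp(vit$score - log_partition(em, model$transitions))
}

#' Save / load a tagger checkpoint
#'
#' A single serialized file holding config, parameters and vocabularies.
#' Loading refuses a checkpoint whose fingerprint does not match its own
#' stored vocabularies (corruption guard), or, when `expect_vocab` is given,
#' whose token vocabulary differs from the expectation.
#'
#' @param model A `phi_tagger`.
#' @param path Checkpoint path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_tagger <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_tagger
#' @param expect_vocab Optional token vocabulary the checkpoint must match.
#' @export
load_tagger <- function(path, expect_vocab = NULL) {
  obj <- readRDS(path)
  fp <- model_fingerprint(obj$encoder$config, obj$token_vocab, obj$label_vocab)
  if (!identical(fp, obj$fingerprint)) stop("checkpoint fingerprint mismatch")
  if (!is.null(expect_vocab) && !identical(obj$token_vocab, expect_vocab)) {
    stop("checkpoint token vocabulary does not match the expected vocabulary")
  }
  class(obj) <- "phi_tagger"
  obj
}

#' Deidentify sentences by surrogate replacement
#'
#' Runs the tagger, then replaces every predicted PHI span with a surrogate
#' mention of the same category drawn (seeded) from the pool. Surrogates are
#' length-free; the replacement log preserves the alignment and the original
#' tokens, so the operation is reversible from the log.
#'
#' @param model A `phi_tagger`.
#' @param sentences List of character token vectors.
#' @param pool A surrogate pool from [make_surrogates()].
#' @param seed Seed for surrogate choice.
#' @return List with `sentences` (redacted token vectors) and `log`
#'   (`data.frame`: sentence, start, end, category, original, surrogate_id,
#'   surrogate).
#' @export
deidentify <- function(model, sentences, pool, seed) {
  pred <- predict_corpus(model, sentences)
  needed <- unique(unlist(lapply(pred$sentences,
                                 function(s) sentence_entities(s)$category)))
  missing_cat <- setdiff(needed, names(pool))
  if (length(missing_cat) > 0) {
    stop(sprintf("surrogate pool missing categories: %s",
                 paste(missing_cat, collapse = ", ")))
  }
  log_rows <- list()
  out <- with_seed(seed, {
    lapply(seq_along(pred$sentences), function(si) {
      s <- pred$sentences[[si]]
      sp <- sentence_entities(s)
      if (nrow(sp) == 0) return(s$tokens)
      tokens <- s$tokens
      # replace right-to-left so earlier offsets stay valid
      for (i in rev(seq_len(nrow(sp)))) {
        cat_i <- sp$category[i]
        choice <- sample.int(length(pool[[cat_i]]), 1)
        surrogate <- pool[[cat_i]][[choice]]
        orig <- tokens[(sp$start[i] + 1L):sp$end[i]]
        tokens <- append(tokens[-((sp$start[i] + 1L):sp$end[i])],
                         surrogate, after = sp$start[i])
        log_rows[[length(log_rows) + 1L]] <<- data.frame(
          sentence = si, start = sp$start[i], end = sp$end[i],
          category = cat_i, original = paste(orig, collapse = " "),
          surrogate_id = choice,
          surrogate = paste(surrogate, collapse = " "),
          stringsAsFactors = FALSE)
      }
      tokens
    })
  })
  log_df <- if (length(log_rows) > 0) do.call(rbind, rev(log_rows)) else {
    data.frame(sentence = integer(), start = integer(), end = integer(),
               category = character(), original = character(),
               surrogate_id = integer(), surrogate = character())
  }
  list(sentences = out, log = log_df)
}

#' Annotation bootstrapping from a small labeled seed set
#'
#' Emulates the annotate-10%-then-propagate workflow: train a tagger on the
#' labeled mini corpus, predict on the unlabeled corpus, and flag
#' low-confidence sentences (normalized Viterbi path probability below a
#' threshold) for manual review.
#'
#' @param mini Labeled `phi_corpus` (the manually annotated fraction).
#' @param unlabeled List of character token vectors.
#' @param config [encoder_config()] for the bootstrap tagger.
#' @param train_config [tagger_train_config()].
#' @param threshold Confidence threshold below which a sentence is flagged.
#' @return List with `annotated` (`phi_corpus` of predictions), `confidence`
#'   (numeric per sentence), `flagged` (logical per sentence), `model`.
#' @export
bootstrap_annotate <- function(mini, unlabeled, config,
                               train_config = tagger_train_config(),
                               threshold = 0.5) {
  if (length(mini$sentences) < 2) stop("mini corpus too small to build a vocabulary")
  model <- train_tagger(mini, config, train_config)
  annotated <- predict_corpus(model, unlabeled)
  confidence <- vapply(unlabeled, function(tk) path_confidence(model, tk),
                       numeric(1))
  list(annotated = annotated, confidence = confidence,
       flagged = confidence < threshold, model = model)
}
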