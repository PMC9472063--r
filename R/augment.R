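# Hybrid data augmentation: generation-based augmentation (linearize labeled
# sentences into mixed label/token streams, fit a next-token language model,
# sample new streams, delinearize and filter) plus mention replacement.

BOS_SYM <- "<bos>"
EOS_SYM <- "<eos>"

#' Augmentation configuration
#'
#' @param daga_sample_count Generated-sentence budget for the generation
#'   strategy (default 2x the corpus size when `NULL`).
#' @param mr_pass_count Mention-replacement passes over the corpus.
#' @param p Per-entity replacement probability (default 0.5).
#' @param max_len Maximum generated stream length.
#' @param temperature Sampling temperature for generation.
#' @param lm_epochs,lm_dim,lm_lr Language-model training controls.
#' @param max_attempts_factor Sampling attempts allowed per requested
#'   sentence before giving up.
#' @param seed Seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(daga_sample_count = NULL, mr_pass_count = 2L,
                                p = 0.5, max_len = 40L, temperature = 1,
                                lm_epochs = 15L, lm_dim = 24L, lm_lr = 0.1,
                                max_attempts_factor = 10L, seed = 1L) {
  if (p < 0 || p > 1) stop("replacement probability must be in [0, 1]")
  if (!is.null(daga_sample_count) && daga_sample_count < 0) {
    stop("daga_sample_count must be >= 0")
  }
  if (mr_pass_count < 0) stop("mr_pass_count must be >= 0")
  structure(list(daga_sample_count = daga_sample_count,
                 mr_pass_count = as.integer(mr_pass_count), p = p,
                 max_len = as.integer(max_len), temperature = temperature,
                 lm_epochs = as.integer(lm_epochs),
                 lm_dim = as.integer(lm_dim), lm_lr = lm_lr,
                 max_attempts_factor = as.integer(max_attempts_factor),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Linearize a labeled sentence into a mixed label/token stream
#'
#' Every non-`O` token is immediately preceded by its tag marker (`B-` and
#' `I-` markers are both emitted); `O` tokens appear bare. Order is
#' preserved, so [delinearize()] inverts the operation exactly.
#'
#' @param sentence A `labeled_sentence`.
#' @return Character vector: the stream (no terminator symbol).
#' @export
linearize <- function(sentence) {
  out <- character(0)
  for (i in seq_along(sentence$tokens)) {
    if (sentence$tags[i] != "O") out <- c(out, sentence$tags[i])
    out <- c(out, sentence$tokens[i])
  }
  out
}

is_marker <- function(x) grepl("^[BI]-.+$", x)

#' Delinearize a sampled stream back into a labeled sentence
#'
#' Operates on raw sampled streams; malformation is a structured rejection,
#' not an error. Accepted outputs always pass [validate_bio()].
#'
#' @param stream Character vector of markers and surface tokens.
#' @return List: `ok = TRUE` plus `sentence`, or `ok = FALSE` plus `reason`
#'   (one of `"empty"`, `"dangling-marker"`, `"invalid-bio"`).
#' @export
delinearize <- function(stream) {
  stream <- setdiff_keep(stream, c(BOS_SYM, EOS_SYM))
  if (length(stream) == 0) return(list(ok = FALSE, reason = "empty"))
  tokens <- character(0); tags <- character(0)
  i <- 1L
  while (i <= length(stream)) {
    if (is_marker(stream[i])) {
      if (i == length(stream) || is_marker(stream[i + 1L])) {
        return(list(ok = FALSE, reason = "dangling-marker"))
      }
      tokens <- c(tokens, stream[i + 1L])
      tags <- c(tags, stream[i])
      i <- i + 2L
    } else {
      tokens <- c(tokens, stream[i])
      tags <- c(tags, "O")
      i <- i + 1L
    }
  }
  if (length(validate_bio(tags)) > 0) {
    return(list(ok = FALSE, reason = "invalid-bio"))
  }
  list(ok = TRUE, sentence = labeled_sentence(tokens, tags, source = "daga"))
}

# drop given symbols while keeping order
setdiff_keep <- function(x, drop) x[!(x %in% drop)]

#' Fit the stream language model
#'
#' A low-rank next-token model over the joint marker/token vocabulary:
#' each input symbol is embedded (`e_t`), mapped through a learned weight
#' matrix (`h_t = M e_t`), and projected to a softmax over the vocabulary to
#' predict the following symbol. Trained by maximizing next-token
#' log-likelihood with Adam.
#'
#' @param streams List of linearized streams (without terminator; `<bos>` /
#'   `<eos>` are added internally).
#' @param config An [augmentation_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return An `lm_params` object: embeddings, recurrence matrix `M`, output
#'   projection, vocabulary, and the per-epoch mean NLL trace.
#' @export
train_lm <- function(streams, config = augmentation_config(),
                     seed = config$seed) {
  if (length(streams) == 0) stop("empty corpus")
  vocab <- sort(unique(unlist(streams)))
  vocab <- c(BOS_SYM, EOS_SYM, setdiff(vocab, c(BOS_SYM, EOS_SYM)))
  V <- length(vocab)
  if (V < 2) stop("vocabulary too small")
  m <- config$lm_dim
  enc <- lapply(streams, function(s) match(c(BOS_SYM, s, EOS_SYM), vocab))
  with_seed(seed, {
    par <- list(emb = rnorm_mat(V, m, sd = 0.1), M = rnorm_mat(m, m, sd = 0.1),
                U = rnorm_mat(m, V, sd = 0.1), b = numeric(V))
    opt <- adam_init(par)
    trace <- numeric(config$lm_epochs)
    for (epoch in seq_len(config$lm_epochs)) {
      total <- 0; n_tok <- 0
      for (ids in enc[sample.int(length(enc))]) {
        inp <- ids[-length(ids)]; out <- ids[-1]
        E <- par$emb[inp, , drop = FALSE]
        H <- E %*% par$M
        logits <- sweep(H %*% par$U, 2, par$b, "+")
        P <- row_softmax(logits)
        nll <- -sum(log(pmax(P[cbind(seq_along(out), out)], 1e-12)))
        total <- total + nll; n_tok <- n_tok + length(out)
        gL <- P
        gL[cbind(seq_along(out), out)] <- gL[cbind(seq_along(out), out)] - 1
        gL <- gL / length(out)
        g <- list(emb = matrix(0, V, m), M = t(E) %*% (gL %*% t(par$U)),
                  U = t(H) %*% gL, b = colSums(gL))
        gE <- (gL %*% t(par$U)) %*% t(par$M)
        g$emb <- rowsum_into(gE, inp, V)
        upd <- adam_step(par, g, opt, lr = config$lm_lr)
        par <- upd$par; opt <- upd$state
      }
      trace[epoch] <- total / n_tok
    }
    structure(list(par = par, vocab = vocab, dim = m, trace = trace),
              class = "lm_params")
  })
}

#' @export
print.lm_params <- function(x, ...) {
  cat(sprintf("<lm_params> vocab %d, dim %d, final NLL/token %.3f\n",
              length(x$vocab), x$dim, utils::tail(x$trace, 1)))
  invisible(x)
}

#' Next-symbol distribution of the stream language model
#'
#' @param lm An `lm_params`.
#' @param symbol Conditioning symbol (must be in the vocabulary).
#' @param temperature Softmax temperature.
#' @return Named probability vector over the vocabulary (sums to 1).
#' @export
lm_next_distribution <- function(lm, symbol, temperature = 1) {
  i <- match(symbol, lm$vocab)
  if (is.na(i)) stop(sprintf("symbol not in vocabulary: %s", symbol))
  h <- lm$par$emb[i, , drop = FALSE] %*% lm$par$M
  logits <- drop(h %*% lm$par$U) + lm$par$b
  if (temperature <= 0) {
    # argmax limit
    p <- numeric(length(logits)); p[which.max(logits)] <- 1
  } else {
    z <- logits / temperature
    p <- exp(z - max(z)); p <- p / sum(p)
  }
  stats::setNames(p, lm$vocab)
}

sample_stream <- function(lm, max_len, temperature) {
  cur <- BOS_SYM
  out <- character(0)
  for (i in seq_len(max_len)) {
    p <- lm_next_distribution(lm, cur, temperature)
    nxt <- if (temperature <= 0) names(p)[which.max(p)] else {
      sample(lm$vocab, 1, prob = p)
    }
    if (nxt == EOS_SYM) break
    if (nxt != BOS_SYM) out <- c(out, nxt)
    cur <- nxt
  }
  out
}

#' Generation-based augmentation
#'
#' Linearizes the corpus, trains (or reuses) the stream language model,
#' samples new streams, delinearizes, and keeps only sentences passing BIO
#' validation. At most `max_attempts_factor * count` samples are drawn.
#'
#' @param corpus A `phi_corpus`.
#' @param config An [augmentation_config()].
#' @param lm Optional pre-trained `lm_params`.
#' @return List: `sentences` (accepted `labeled_sentence`s, source
#'   `"daga"`), `stats` (attempts and rejects by reason), `lm`.
#' @export
daga_augment <- function(corpus, config = augmentation_config(), lm = NULL) {
  count <- config$daga_sample_count
  if (is.null(count)) count <- 2L * length(corpus$sentences)
  streams <- lapply(corpus$sentences, linearize)
  if (is.null(lm)) lm <- train_lm(streams, config, seed = config$seed)
  rejects <- c(empty = 0L, `dangling-marker` = 0L, `invalid-bio` = 0L)
  accepted <- list()
  attempts <- 0L
  max_attempts <- config$max_attempts_factor * max(count, 1L)
  with_seed(config$seed + 1L, {
    while (length(accepted) < count && attempts < max_attempts) {
      attempts <- attempts + 1L
      st <- sample_stream(lm, config$max_len, config$temperature)
      res <- delinearize(st)
      if (res$ok) {
        accepted[[length(accepted) + 1L]] <- res$sentence
      } else {
        rejects[res$reason] <- rejects[res$reason] + 1L
      }
    }
  })
  if (count > 0 && length(accepted) == 0) {
    warning("generation produced no valid sentences within the attempt budget")
  }
  list(sentences = accepted,
       stats = list(requested = count, attempts = attempts,
                    accepted = length(accepted), rejects = rejects),
       lm = lm)
}

#' Mention replacement
#'
#' For each entity an independent Bernoulli(`p`) decision selects it for
#' replacement by a uniformly drawn same-category mention from the corpus
#' entity pool (excluding the identical mention when the pool allows).
#' Tags re-expand to the replacement's length, so outputs stay valid BIO.
#'
#' @param corpus A `phi_corpus` (also the source of the entity pools).
#' @param config An [augmentation_config()] (`p`, `mr_pass_count`, `seed`).
#' @return List: `sentences` (new `labeled_sentence`s, source `"mr"`,
#'   `mr_pass_count` per original sentence), `decisions` (total Bernoulli
#'   draws) and `replaced` (how many chose replacement).
#' @export
mention_replace <- function(corpus, config = augmentation_config()) {
  pools <- entity_pools(corpus)
  decisions <- 0L; replaced <- 0L
  out <- list()
  with_seed(config$seed + 2L, {
    for (pass in seq_len(config$mr_pass_count)) {
      for (s in corpus$sentences) {
        sp <- sentence_entities(s)
        tokens <- s$tokens; tags <- s$tags
        if (nrow(sp) > 0) for (i in rev(seq_len(nrow(sp)))) {
          decisions <- decisions + 1L
          if (stats::runif(1) >= config$p) next
          cat_i <- sp$category[i]
          pool <- pools[[cat_i]]
          idx <- (sp$start[i] + 1L):sp$end[i]
          orig_key <- paste(tokens[idx], collapse = "\u1f")
          candidates <- pool[names(pool) != orig_key]
          if (length(candidates) == 0) next  # empty pool: keep, counted as kept
          replaced <- replaced + 1L
          repl <- candidates[[sample.int(length(candidates), 1)]]
          tokens <- append(tokens[-idx], repl, after = sp$start[i])
          tags <- append(tags[-idx],
                         c(paste0("B-", cat_i),
                           rep(paste0("I-", cat_i), length(repl) - 1L)),
                         after = sp$start[i])
        }
        out[[length(out) + 1L]] <- labeled_sentence(tokens, tags, source = "mr")
      }
    }
  })
  list(sentences = out, decisions = decisions, replaced = replaced)
}

# unique mentions per category, keyed by their token sequence
entity_pools <- function(corpus) {
  pools <- stats::setNames(vector("list", length(corpus$categories)),
                           corpus$categories)
  for (c_i in corpus$categories) pools[[c_i]] <- list()
  for (s in corpus$sentences) {
    sp <- sentence_entities(s)
    for (i in seq_len(nrow(sp))) {
      mention <- s$tokens[(sp$start[i] + 1L):sp$end[i]]
      key <- paste(mention, collapse = "\u1f")
      pools[[sp$category[i]]][[key]] <- mention
    }
  }
  pools
}

#' Hybrid augmentation
#'
#' Combines the original training sentences with generation-based and
#' mention-replacement sentences; per-sentence provenance is retained and a
#' per-category, per-source entity summary is reported. Evaluation/test
#' corpora are never passed through this function.
#'
#' @param corpus Training `phi_corpus`.
#' @param config An [augmentation_config()].
#' @return List: `corpus` (augmented `phi_corpus`), `summary` (`data.frame`
#'   category x original/daga/mr/total entity counts), `daga_stats`.
#' @export
hybrid_augment <- function(corpus, config = augmentation_config()) {
  daga <- if (is.null(config$daga_sample_count) ||
              config$daga_sample_count > 0) {
    daga_augment(corpus, config)
  } else list(sentences = list(), stats = NULL)
  mr <- if (config$mr_pass_count > 0) mention_replace(corpus, config) else {
    list(sentences = list())
  }
  all_sentences <- c(corpus$sentences, daga$sentences, mr$sentences)
  aug <- phi_corpus(all_sentences, categories = corpus$categories)
  count_by <- function(sentences) {
    cnt <- stats::setNames(integer(length(corpus$categories)),
                           corpus$categories)
    for (s in sentences) {
      sp <- sentence_entities(s)
      if (nrow(sp) > 0) {
        tb <- table(factor(sp$category, levels = corpus$categories))
        cnt <- cnt + as.integer(tb)
      }
    }
    cnt
  }
  summary <- data.frame(category = corpus$categories,
                        original = as.integer(count_by(corpus$sentences)),
                        daga = as.integer(count_by(daga$sentences)),
                        mr = as.integer(count_by(mr$sentences)))
  summary$total <- summary$original + summary$daga + summary$mr
  list(corpus = aug, summary = summary, daga_stats = daga$stats)
}

#' Write augmented sentences with a provenance sidecar
#'
#' Sentences go to CoNLL; a JSON-lines sidecar records per-sentence source
#' and the run seed.
#'
#' @param corpus Augmented `phi_corpus`.
#' @param conll_path,jsonl_path Output paths.
#' @param seed Seed recorded in the sidecar.
#' @return `conll_path`, invisibly.
#' @export
write_augmented <- function(corpus, conll_path, jsonl_path, seed = NA) {
  write_conll(corpus, conll_path)
  lines <- vapply(seq_along(corpus$sentences), function(i) {
    jsonlite::toJSON(list(index = i, source = corpus$sentences[[i]]$source,
                          seed = seed), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, jsonl_path, useBytes = TRUE)
  invisible(conll_path)
}
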