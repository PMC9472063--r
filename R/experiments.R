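# Packaged experiment protocols: distillation benefit and hybrid
# augmentation benefit on synthetic corpora. Both are directional studies —
# they compare mean entity-level micro-F1 across fixed seeds rather than
# reproducing any absolute score.

#' Distillation-benefit experiment
#'
#' Trains an M-layer teacher tagger on the training split, then for each
#' seed: (a) distills a freshly initialized N-layer student from the
#' teacher and (b) randomly initializes a same-shape student; both students
#' then receive an identical supervised fine-tuning schedule, and both are
#' scored on the held-out test split by entity-level micro-F1.
#'
#' @param corpus A `phi_corpus` (split 6:2:2 internally).
#' @param teacher_config,student_config [encoder_config()]s; the student
#'   layer count must divide the teacher's.
#' @param seeds Integer vector of experiment seeds.
#' @param teacher_train [tagger_train_config()] for the teacher.
#' @param distill_epochs Distillation passes over the training split.
#' @param finetune_epochs Supervised fine-tuning epochs given identically to
#'   both students.
#' @param split_seed Seed for the corpus split.
#' @return `data.frame` with one row per seed: `f1_distilled`, `f1_random`,
#'   and the teacher's test F1 in attribute `"teacher_f1"`.
#' @export
distillation_benefit <- function(corpus, teacher_config, student_config,
                                 seeds = 1:3,
                                 teacher_train = tagger_train_config(
                                   epochs = 8L, lr = 5e-3, seed = 100L),
                                 distill_epochs = 3L,
                                 finetune_epochs = 1L,
                                 split_seed = 42L) {
  parts <- split_corpus(corpus, seed = split_seed)
  teacher <- train_tagger(parts$train, teacher_config, teacher_train,
                          eval = parts$eval)
  teacher_f1 <- eval_f1(teacher, parts$test)
  rows <- lapply(seeds, function(sd) {
    distilled <- distill(teacher, student_config, parts$train,
                         epochs = distill_epochs, seed = sd, lr = 5e-3)
    random_student <- random_student_like(teacher, student_config, seed = sd)
    ft_cfg <- tagger_train_config(epochs = finetune_epochs, lr = 5e-3,
                                  seed = sd)
    distilled_ft <- finetune_tagger(distilled, parts$train, ft_cfg)
    random_ft <- finetune_tagger(random_student, parts$train, ft_cfg)
    data.frame(seed = sd,
               f1_distilled = eval_f1(distilled_ft, parts$test),
               f1_random = eval_f1(random_ft, parts$test))
  })
  out <- do.call(rbind, rows)
  attr(out, "teacher_f1") <- teacher_f1
  out
}

eval_f1 <- function(model, corpus) {
  pred <- predict_corpus(model, corpus)
  unname(score_entities(match_entities(corpus, pred))$micro["f1"])
}

random_student_like <- function(teacher, student_config, seed) {
  cfg <- student_config
  cfg$vocab_size <- teacher$encoder$config$vocab_size
  cfg$n_labels <- teacher$encoder$config$n_labels
  cfg$max_len <- teacher$encoder$config$max_len
  cfg$n_heads <- teacher$encoder$config$n_heads
  cfg$seed <- as.integer(seed) + 7777L
  enc <- init_encoder(cfg)
  new_tagger(enc, init_transitions(cfg$n_labels, "zero"),
             teacher$token_vocab, teacher$label_vocab, teacher$categories)
}

#' Continue supervised training from an existing tagger
#'
#' Same objective and optimizer as [train_tagger()] but starting from the
#' model's current parameters (fresh Adam state).
#'
#' @param model A `phi_tagger`.
#' @param train Training `phi_corpus` (must share the model vocabularies).
#' @param train_config A [tagger_train_config()].
#' @return The fine-tuned `phi_tagger`.
#' @export
finetune_tagger <- function(model, train, train_config) {
  if (train_config$epochs == 0) return(model)
  if (!identical(train$label_vocab, model$label_vocab)) {
    stop("label vocabulary mismatch")
  }
  encoder <- model$encoder
  params <- list(enc = encoder$par, tr = model$transitions)
  opt <- adam_init(params)
  batches <- prepare_batches(train, model$token_vocab, model$label_vocab,
                             encoder$config$max_len)
  n <- length(batches)
  with_seed(train_config$seed, {
    for (epoch in seq_len(train_config$epochs)) {
      order_idx <- sample.int(n)
      i <- 1L
      while (i <= n) {
        take <- order_idx[i:min(i + train_config$batch_size - 1L, n)]
        g_acc <- NULL
        for (j in take) {
          encoder$par <- params$enc
          sl <- sentence_loss_grad(encoder, params$tr, batches[[j]]$batch,
                                   batches[[j]]$tag_ids)
          g <- list(enc = sl$g_enc, tr = sl$g_tr)
          g_acc <- if (is.null(g_acc)) g else add_params(g_acc, g)
        }
        g_acc <- scale_params(g_acc, 1 / length(take))
        upd <- adam_step(params, g_acc, opt, lr = train_config$lr)
        params <- upd$par; opt <- upd$state
        i <- i + train_config$batch_size
      }
    }
  })
  encoder$par <- params$enc
  new_tagger(encoder, params$tr, model$token_vocab, model$label_vocab,
             model$categories)
}

#' Hybrid-augmentation-benefit experiment
#'
#' For each seed, trains the same tagger configuration on (a) the
#' hybrid-augmented training split and (b) a 50% subsample of the raw
#' training split, and scores both on the untouched test split. The
#' evaluation and test splits are never augmented.
#'
#' @param corpus A `phi_corpus`.
#' @param config [encoder_config()] for the taggers.
#' @param seeds Integer vector of experiment seeds.
#' @param subsample_frac Fraction of the raw training split for the
#'   comparison arm (default 0.5).
#' @param epochs,lr Training schedule shared by both arms.
#' @param aug_config [augmentation_config()] for the hybrid set.
#' @param split_seed Seed for the corpus split.
#' @return `data.frame` with one row per seed: `f1_hybrid`,
#'   `f1_subsample`; the augmentation summary table is in attribute
#'   `"aug_summary"`.
#' @export
hybrid_benefit <- function(corpus, config, seeds = 1:3,
                           subsample_frac = 0.5, epochs = 6L, lr = 5e-3,
                           aug_config = augmentation_config(),
                           split_seed = 42L) {
  parts <- split_corpus(corpus, seed = split_seed)
  aug <- hybrid_augment(parts$train, aug_config)
  rows <- lapply(seeds, function(sd) {
    sub_idx <- with_seed(sd + 5000L, {
      sample.int(length(parts$train$sentences),
                 max(1L, round(subsample_frac * length(parts$train$sentences))))
    })
    subsample <- phi_corpus(parts$train$sentences[sub_idx],
                            categories = parts$train$categories)
    tc <- tagger_train_config(epochs = epochs, lr = lr, seed = sd)
    m_hybrid <- train_tagger(aug$corpus, config, tc, eval = parts$eval)
    m_sub <- train_tagger(subsample, config, tc, eval = parts$eval)
    data.frame(seed = sd,
               f1_hybrid = eval_f1(m_hybrid, parts$test),
               f1_subsample = eval_f1(m_sub, parts$test))
  })
  out <- do.call(rbind, rows)
  attr(out, "aug_summary") <- aug$summary
  out
}
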