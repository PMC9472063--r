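test_that("linearize places a marker before every non-O token", {
  s <- labeled_sentence(c("t1", "t2", "t3"), c("B-PER", "I-PER", "O"))
  expect_equal(linearize(s), c("B-PER", "t1", "I-PER", "t2", "t3"))
  s_o <- labeled_sentence(c("x", "y"), c("O", "O"))
  expect_equal(linearize(s_o), c("x", "y"))
})

test_that("delinearize inverts linearize and rejects malformed streams", {
  r <- delinearize(c("B-DAT", "t1", "I-DAT", "t2"))
  expect_true(r$ok)
  expect_equal(r$sentence$tags, c("B-DAT", "I-DAT"))
  expect_false(delinearize(c("I-PER", "t1"))$ok)
  expect_equal(delinearize(c("I-PER", "t1"))$reason, "invalid-bio")
  expect_equal(delinearize(c("B-PER", "B-PER", "t1"))$reason, "dangling-marker")
  expect_equal(delinearize(c("t1", "B-PER"))$reason, "dangling-marker")
  expect_equal(delinearize(character(0))$reason, "empty")
  set.seed(12)
  for (i in 1:100) {
    s <- random_sentence()
    back <- delinearize(linearize(s))
    expect_true(back$ok)
    expect_equal(back$sentence$tokens, s$tokens)
    expect_equal(back$sentence$tags, s$tags)
  }
})

test_that("the stream language model learns a degenerate bigram corpus", {
  streams <- rep(list(c("w1", "w2")), 30)
  lm <- train_lm(streams, augmentation_config(lm_epochs = 60, lm_dim = 8),
                 seed = 4)
  p <- lm_next_distribution(lm, "w1")
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_gt(p[["w2"]], 0.9)
  # training loss decreases
  expect_lt(tail(lm$trace, 1), lm$trace[1])
  # determinism
  lm2 <- train_lm(streams, augmentation_config(lm_epochs = 60, lm_dim = 8),
                  seed = 4)
  expect_identical(lm$par, lm2$par)
  # distributions sum to 1 across conditioning symbols
  for (sym in lm$vocab) {
    expect_equal(sum(lm_next_distribution(lm, sym)), 1, tolerance = 1e-6)
  }
  expect_error(train_lm(list(), augmentation_config()), "empty")
})

test_that("argmax sampling on a one-bigram corpus regenerates the sentence", {
  s <- labeled_sentence(c("w1", "w2"), c("B-PER", "I-PER"))
  co <- phi_corpus(rep(list(s), 20))
  cfg <- augmentation_config(daga_sample_count = 3, temperature = 0,
                             lm_epochs = 80, lm_dim = 8, seed = 6)
  res <- daga_augment(co, cfg)
  expect_gte(length(res$sentences), 1)
  for (g in res$sentences) {
    expect_equal(g$tokens, s$tokens)
    expect_equal(g$tags, s$tags)
  }
})

test_that("generated sentences are all BIO-valid and reproducible", {
  set.seed(90)
  co <- phi_corpus(replicate(40, random_sentence(), simplify = FALSE))
  cfg <- augmentation_config(daga_sample_count = 60, seed = 8, lm_epochs = 8)
  res <- daga_augment(co, cfg)
  expect_gt(length(res$sentences), 0)
  for (g in res$sentences) {
    expect_length(validate_bio(g$tags), 0)
    expect_equal(g$source, "daga")
  }
  expect_equal(res$stats$accepted + sum(res$stats$rejects),
               res$stats$attempts)
  res2 <- daga_augment(co, cfg)
  expect_identical(lapply(res$sentences, `[[`, "tokens"),
                   lapply(res2$sentences, `[[`, "tokens"))
})

test_that("mention replacement respects the Bernoulli boundaries", {
  set.seed(14)
  co <- phi_corpus(replicate(30, random_sentence(), simplify = FALSE))
  # p = 0: output equals input
  r0 <- mention_replace(co, augmentation_config(p = 0, mr_pass_count = 1,
                                                seed = 3))
  expect_equal(lapply(r0$sentences, `[[`, "tokens"),
               lapply(co$sentences, `[[`, "tokens"))
  expect_equal(r0$replaced, 0)
  # p = 1: every entity with a non-self candidate is replaced
  r1 <- mention_replace(co, augmentation_config(p = 1, mr_pass_count = 1,
                                                seed = 3))
  expect_equal(r1$decisions, sum(vapply(co$sentences, function(s)
    nrow(sentence_entities(s)), integer(1))))
  expect_gt(r1$replaced / r1$decisions, 0.95)
  # outputs remain valid BIO with preserved categories
  for (s in r1$sentences) expect_length(validate_bio(s$tags), 0)
  cats_in <- sort(unlist(lapply(co$sentences,
                                function(s) sentence_entities(s)$category)))
  cats_out <- sort(unlist(lapply(r1$sentences,
                                 function(s) sentence_entities(s)$category)))
  expect_equal(cats_out, cats_in)
})

test_that("replacement frequency concentrates at p = 0.5", {
  set.seed(15)
  co <- phi_corpus(replicate(120, random_sentence(len = 10), simplify = FALSE))
  r <- mention_replace(co, augmentation_config(p = 0.5, mr_pass_count = 4,
                                               seed = 21))
  expect_gte(r$decisions, 1000)
  rate <- r$replaced / r$decisions
  band <- 3 * sqrt(0.25 / r$decisions)
  expect_gt(rate, 0.5 - band)
  expect_lt(rate, 0.5 + band)
})

test_that("hybrid augmentation keeps the original set and reports sources", {
  set.seed(16)
  co <- phi_corpus(replicate(25, random_sentence(), simplify = FALSE))
  cfg <- augmentation_config(daga_sample_count = 20, mr_pass_count = 1,
                             seed = 2, lm_epochs = 8)
  hy <- hybrid_augment(co, cfg)
  expect_gt(length(hy$corpus$sentences), length(co$sentences))
  key <- function(s) paste(c(s$tokens, s$tags), collapse = "|")
  orig_keys <- vapply(co$sentences, key, character(1))
  aug_keys <- vapply(hy$corpus$sentences, key, character(1))
  expect_true(all(orig_keys %in% aug_keys))
  src <- vapply(hy$corpus$sentences, `[[`, character(1), "source")
  expect_setequal(unique(src), c("original", "daga", "mr"))
  expect_equal(hy$summary$total,
               hy$summary$original + hy$summary$daga + hy$summary$mr)
  # identity when both strategies are disabled
  hy0 <- hybrid_augment(co, augmentation_config(daga_sample_count = 0,
                                                mr_pass_count = 0))
  expect_equal(length(hy0$corpus$sentences), length(co$sentences))
})

test_that("augmented corpora serialize with a provenance sidecar", {
  set.seed(17)
  co <- phi_corpus(replicate(10, random_sentence(), simplify = FALSE))
  cfg <- augmentation_config(daga_sample_count = 5, mr_pass_count = 1,
                             seed = 2, lm_epochs = 5)
  hy <- hybrid_augment(co, cfg)
  f1 <- withr::local_tempfile(fileext = ".conll")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_augmented(hy$corpus, f1, f2, seed = 2)
  back <- read_conll(f1)
  expect_length(back$sentences, length(hy$corpus$sentences))
  prov <- lapply(readLines(f2), jsonlite::fromJSON)
  expect_length(prov, length(hy$corpus$sentences))
  expect_setequal(unique(vapply(prov, `[[`, character(1), "source")),
                  c("original", "daga", "mr"))
})
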