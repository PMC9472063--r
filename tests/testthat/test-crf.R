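test_that("sequence_score sums emission and transition terms", {
  tr <- init_transitions(2)
  em <- matrix(c(2, -1), 1, 2)
  sc <- sequence_score(em, tr, 1L)
  expect_equal(sc$total, 2)
  expect_equal(sc$total, sc$emission_score + sc$transition_score)

  # all-zero scores: any path totals 0
  em0 <- matrix(0, 3, 2)
  for (p in list(c(1, 1, 1), c(2, 1, 2))) {
    expect_equal(sequence_score(em0, tr, p)$total, 0)
  }

  # random instance vs direct hand summation
  set.seed(21)
  em <- matrix(rnorm(6), 3, 2)
  tr <- init_transitions(2, "random", seed = 4)
  tags <- c(2L, 1L, 2L)
  hand <- em[1, 2] + em[2, 1] + em[3, 2] +
    tr[3, 2] + tr[2, 1] + tr[1, 2] + tr[2, 4]
  expect_equal(sequence_score(em, tr, tags)$total, hand)
  expect_error(sequence_score(em, tr, c(1L, 5L, 1L)), "unknown tag")
})

test_that("log_partition equals brute-force enumeration and shifts additively", {
  expect_equal(log_partition(matrix(0, 1, 2), init_transitions(2)), log(2))
  set.seed(77)
  for (i in 1:30) {
    L <- sample(1:5, 1); K <- sample(2:4, 1)
    em <- matrix(rnorm(L * K), L, K)
    tr <- init_transitions(K, "random", seed = i)
    expect_equal(log_partition(em, tr), brute_logZ(em, tr), tolerance = 1e-9)
    # adding c to every emission at one position shifts logZ by exactly c
    pos <- sample(L, 1); cshift <- rnorm(1)
    em2 <- em; em2[pos, ] <- em2[pos, ] + cshift
    expect_equal(log_partition(em2, tr), log_partition(em, tr) + cshift,
                 tolerance = 1e-9)
  }
  expect_error(log_partition(matrix(numeric(0), 0, 2), init_transitions(2)),
               "empty")
})

test_that("nll is the gold path's negative normalized log-probability", {
  set.seed(13)
  for (i in 1:15) {
    L <- sample(1:4, 1); K <- sample(2:4, 1)
    em <- matrix(rnorm(L * K), L, K)
    tr <- init_transitions(K, "random", seed = 100 + i)
    tags <- sample(K, L, replace = TRUE)
    nll <- crf_nll(em, tr, tags)
    expect_gte(nll, 0)
    all_sc <- brute_all_scores(em, tr)
    gold_sc <- sequence_score(em, tr, tags)$total
    expect_equal(exp(-nll), exp(gold_sc) / sum(exp(all_sc)), tolerance = 1e-9)
    # path probabilities normalize to 1
    logZ <- log_partition(em, tr)
    expect_equal(sum(exp(all_sc - logZ)), 1, tolerance = 1e-9)
  }
})

test_that("nll gradients match finite differences", {
  set.seed(55)
  em <- matrix(rnorm(8), 4, 2)
  tr <- init_transitions(2, "random", seed = 9)
  tags <- c(1L, 2L, 2L, 1L)
  g <- phideid:::crf_nll_grad(em, tr, tags)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 2), c(4, 1))) {
    em2 <- em; em2[idx[1], idx[2]] <- em2[idx[1], idx[2]] + eps
    em3 <- em; em3[idx[1], idx[2]] <- em3[idx[1], idx[2]] - eps
    num <- (crf_nll(em2, tr, tags) - crf_nll(em3, tr, tags)) / (2 * eps)
    expect_equal(g$emissions[idx[1], idx[2]], num, tolerance = 1e-5)
  }
  for (idx in list(c(1, 2), c(2, 1), c(3, 1))) {
    tr2 <- tr; tr2[idx[1], idx[2]] <- tr2[idx[1], idx[2]] + eps
    tr3 <- tr; tr3[idx[1], idx[2]] <- tr3[idx[1], idx[2]] - eps
    num <- (crf_nll(em, tr2, tags) - crf_nll(em, tr3, tags)) / (2 * eps)
    expect_equal(g$transitions[idx[1], idx[2]], num, tolerance = 1e-5)
  }
})

test_that("viterbi equals exhaustive argmax with the same tie-break", {
  set.seed(41)
  for (i in 1:30) {
    L <- sample(1:5, 1); K <- sample(2:4, 1)
    em <- matrix(rnorm(L * K), L, K)
    tr <- init_transitions(K, "random", seed = 200 + i)
    v <- viterbi(em, tr)
    b <- brute_viterbi(em, tr)
    expect_equal(v$tags, b$tags)
    expect_equal(v$score, b$score, tolerance = 1e-9)
    expect_equal(v$score, sequence_score(em, tr, v$tags)$total,
                 tolerance = 1e-9)
  }
  # L = 1: argmax of emissions + boundary transitions
  em <- matrix(c(1, 3), 1, 2)
  tr <- init_transitions(2)
  expect_equal(viterbi(em, tr)$tags, 2L)
})

test_that("the BIO constraint mask encodes exactly the dependency rules", {
  lv <- bio_label_vocab()   # 4 categories, 9 labels
  m <- bio_constraint_mask(lv)
  expect_true(m["START", "B-PER"])
  expect_false(m["START", "I-PER"])
  expect_true(m["O", "O"])
  # enumerate: an I-X is reachable only from B-X / I-X
  for (cat_i in phi_categories()) {
    itag <- paste0("I-", cat_i)
    allowed_from <- rownames(m)[m[, itag]]
    expect_setequal(allowed_from, paste0(c("B-", "I-"), cat_i))
  }
  expect_false(any(m[, "START"]))
  expect_false(any(m["END", ]))
  expect_error(bio_constraint_mask(c("O", "WRONG")), "non-BIO")
})

test_that("masked decoding never emits invalid BIO transitions", {
  lv <- bio_label_vocab()
  m <- bio_constraint_mask(lv)
  set.seed(17)
  for (i in 1:25) {
    L <- sample(2:8, 1)
    em <- matrix(rnorm(L * length(lv), sd = 3), L, length(lv))
    tr <- init_transitions(length(lv), "random", seed = 300 + i)
    v <- viterbi(em, tr, mask = m)
    tags <- lv[v$tags]
    expect_length(validate_bio(tags), 0)
  }
})

test_that("an all-masked instance reports no feasible path", {
  tr <- init_transitions(2)
  m <- matrix(FALSE, 4, 4)
  expect_error(viterbi(matrix(0, 2, 2), tr, mask = m), "no feasible path")
})

test_that("transition matrices export to JSON with labels and mask", {
  lv <- bio_label_vocab(c("PER"))
  tr <- init_transitions(length(lv))
  f <- withr::local_tempfile(fileext = ".json")
  write_transitions_json(tr, lv, f, mask = bio_constraint_mask(lv))
  obj <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(unlist(obj$labels), c(lv, "START", "END"))
  expect_length(obj$scores, length(lv) + 2)
  expect_length(obj$scores[[1]], length(lv) + 2)
})
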