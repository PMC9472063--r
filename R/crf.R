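# Linear-chain CRF: path scoring, exact log-partition, NLL + gradients,
# and constrained Viterbi decoding.
#
# A path score decomposes as emission_score + transition_score, where the
# transition part includes explicit START and END boundary states. The
# transition matrix is (K+2) x (K+2) with labels 1..K, START = K+1,
# END = K+2; START has no inbound and END no outbound transitions.

MASK_PENALTY <- -1e4  # additive score for disallowed transitions (kept finite)

#' Initialize a transition matrix
#'
#' @param n_labels Number of real labels K.
#' @param init `"zero"` or `"random"` (N(0, 0.01)).
#' @param seed Seed used when `init = "random"`.
#' @return A `(K+2) x (K+2)` numeric matrix with START/END boundary rows set
#'   up (START column and END row are structurally impossible and held at a
#'   large negative constant).
#' @export
init_transitions <- function(n_labels, init = c("zero", "random"), seed = 1) {
  init <- match.arg(init)
  k2 <- n_labels + 2L
  tr <- if (init == "zero") matrix(0, k2, k2) else {
    with_seed(seed, matrix(stats::rnorm(k2 * k2, sd = 0.01), k2, k2))
  }
  start <- n_labels + 1L; end <- n_labels + 2L
  tr[, start] <- MASK_PENALTY   # nothing enters START
  tr[end, ] <- MASK_PENALTY     # nothing leaves END
  tr[start, end] <- MASK_PENALTY
  tr
}

crf_states <- function(transitions) {
  k2 <- nrow(transitions)
  list(K = k2 - 2L, start = k2 - 1L, end = k2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Score a fixed label path
#'
#' The emission part sums the per-position scores of the path's labels; the
#' transition part sums START->tag_1, consecutive tag transitions, and
#' tag_L->END.
#'
#' @param emissions `L x K` matrix of per-position, per-label scores.
#' @param transitions `(K+2) x (K+2)` transition matrix.
#' @param tags Integer vector of label indices (1-based), length L.
#' @return List with `emission_score`, `transition_score`, `total`.
#' @export
sequence_score <- function(emissions, transitions, tags) {
  st <- crf_states(transitions)
  L <- nrow(emissions)
  if (length(tags) != L) stop("tags length must equal number of positions")
  tags <- as.integer(tags)
  if (any(tags < 1 | tags > st$K)) stop("unknown tag index")
  em <- sum(emissions[cbind(seq_len(L), tags)])
  tr <- transitions[st$start, tags[1]] + transitions[tags[L], st$end]
  if (L > 1) {
    tr <- tr + sum(transitions[cbind(tags[-L], tags[-1])])
  }
  list(emission_score = em, transition_score = tr, total = em + tr)
}

#' Exact log-partition function by the forward recursion
#'
#' Computes `log sum over all K^L label paths of exp(sequence_score)` in
#' `O(L K^2)` with log-sum-exp stabilization.
#'
#' @inheritParams sequence_score
#' @return Scalar log-partition value.
#' @export
log_partition <- function(emissions, transitions) {
  st <- crf_states(transitions)
  L <- nrow(emissions)
  if (L == 0) stop("empty sequence")
  if (ncol(emissions) != st$K) stop("emission width must equal label count")
  trKK <- transitions[seq_len(st$K), seq_len(st$K), drop = FALSE]
  alpha <- transitions[st$start, seq_len(st$K)] + emissions[1, ]
  if (L > 1) {
    for (i in 2:L) {
      # alpha_new[j] = logsumexp_k(alpha[k] + tr[k,j]) + em[i,j]
      m <- alpha + trKK            # column j holds alpha + tr[,j]
      mx <- apply(m, 2, max)
      alpha <- mx + log(colSums(exp(sweep(m, 2, mx)))) + emissions[i, ]
    }
  }
  logsumexp(alpha + transitions[seq_len(st$K), st$end])
}

#' Negative log-likelihood of a gold path
#'
#' `nll = log_partition - sequence_score(gold)$total`; always nonnegative,
#' and equal to minus the log of the gold path's normalized probability.
#'
#' @inheritParams sequence_score
#' @return Scalar loss.
#' @export
crf_nll <- function(emissions, transitions, tags) {
  log_partition(emissions, transitions) -
    sequence_score(emissions, transitions, tags)$total
}

# Forward-backward gradients of the NLL.
# Returns d nll / d emissions (L x K) and d nll / d transitions
# ((K+2) x (K+2)): expected feature counts minus gold feature counts.
crf_nll_grad <- function(emissions, transitions, tags) {
  st <- crf_states(transitions)
  L <- nrow(emissions); K <- st$K
  trKK <- transitions[seq_len(K), seq_len(K), drop = FALSE]
  # forward
  alpha <- matrix(0, L, K)
  alpha[1, ] <- transitions[st$start, seq_len(K)] + emissions[1, ]
  if (L > 1) for (i in 2:L) {
    m <- alpha[i - 1, ] + trKK
    mx <- apply(m, 2, max)
    alpha[i, ] <- mx + log(colSums(exp(sweep(m, 2, mx)))) + emissions[i, ]
  }
  logZ <- logsumexp(alpha[L, ] + transitions[seq_len(K), st$end])
  # backward: beta[i,k] = log sum over suffixes starting after position i
  beta <- matrix(0, L, K)
  beta[L, ] <- transitions[seq_len(K), st$end]
  if (L > 1) for (i in (L - 1):1) {
    # beta[i,k] = logsumexp_j(tr[k,j] + em[i+1,j] + beta[i+1,j])
    m <- sweep(trKK, 2, emissions[i + 1, ] + beta[i + 1, ], "+")
    mx <- apply(m, 1, max)
    beta[i, ] <- mx + log(rowSums(exp(m - mx)))
  }
  marg <- exp(alpha + beta - logZ)   # unary marginals
  g_em <- marg
  g_em[cbind(seq_len(L), tags)] <- g_em[cbind(seq_len(L), tags)] - 1
  g_tr <- matrix(0, K + 2L, K + 2L)
  g_tr[st$start, seq_len(K)] <- marg[1, ]
  g_tr[seq_len(K), st$end] <- marg[L, ]
  if (L > 1) for (i in seq_len(L - 1)) {
    # pairwise[a,b] = exp(alpha[i,a] + tr[a,b] + em[i+1,b] + beta[i+1,b] - logZ)
    pw <- exp(outer(alpha[i, ], emissions[i + 1, ] + beta[i + 1, ], "+") +
                trKK - logZ)
    g_tr[seq_len(K), seq_len(K)] <- g_tr[seq_len(K), seq_len(K)] + pw
  }
  g_tr[st$start, tags[1]] <- g_tr[st$start, tags[1]] - 1
  g_tr[tags[L], st$end] <- g_tr[tags[L], st$end] - 1
  if (L > 1) for (i in seq_len(L - 1)) {
    g_tr[tags[i], tags[i + 1]] <- g_tr[tags[i], tags[i + 1]] - 1
  }
  list(emissions = g_em, transitions = g_tr, nll = logZ -
         sequence_score(emissions, transitions, tags)$total)
}

#' Viterbi decoding, optionally under a transition constraint mask
#'
#' Returns the label path maximizing the path score. Disallowed transitions
#' receive a large negative additive penalty rather than true `-Inf`, keeping
#' arithmetic finite. Ties break toward the lowest label index.
#'
#' @inheritParams sequence_score
#' @param mask Optional logical `(K+2) x (K+2)` matrix of allowed
#'   transitions, e.g. from [bio_constraint_mask()].
#' @return List with `tags` (integer path) and `score` (its path score under
#'   the penalized transitions).
#' @export
viterbi <- function(emissions, transitions, mask = NULL) {
  st <- crf_states(transitions)
  L <- nrow(emissions); K <- st$K
  if (L == 0) stop("empty sequence")
  tr <- transitions
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(tr))) stop("mask shape mismatch")
    tr[!mask] <- tr[!mask] + MASK_PENALTY
  }
  trKK <- tr[seq_len(K), seq_len(K), drop = FALSE]
  delta <- tr[st$start, seq_len(K)] + emissions[1, ]
  back <- matrix(0L, L, K)
  if (L > 1) for (i in 2:L) {
    m <- delta + trKK                       # m[k, j]
    best_prev <- apply(m, 2, which.max)     # first max: lowest index wins ties
    delta <- m[cbind(best_prev, seq_len(K))] + emissions[i, ]
    back[i, ] <- best_prev
  }
  final <- delta + tr[seq_len(K), st$end]
  if (all(final <= MASK_PENALTY / 2)) stop("no feasible path")
  last <- which.max(final)
  path <- integer(L)
  path[L] <- last
  if (L > 1) for (i in L:2) path[i - 1L] <- back[i, path[i]]
  list(tags = path, score = final[last])
}

#' BIO transition constraint mask
#'
#' Forbids `START -> I-*`, `O -> I-*`, `B-X -> I-Y` and `I-X -> I-Y` for
#' `X != Y`; all other label transitions are allowed. Boundary
#' impossibilities (into START, out of END) are also forbidden.
#'
#' @param label_vocab Character vector of strict BIO labels
#'   (from [bio_label_vocab()]).
#' @return Logical `(K+2) x (K+2)` matrix of allowed transitions, with
#'   dimnames over labels plus `START`/`END`.
#' @export
bio_constraint_mask <- function(label_vocab) {
  ok <- label_vocab == "O" | grepl("^[BI]-.+$", label_vocab)
  if (!all(ok)) {
    stop(sprintf("non-BIO label in vocabulary: %s",
                 paste(label_vocab[!ok], collapse = ", ")))
  }
  K <- length(label_vocab)
  names_all <- c(label_vocab, "START", "END")
  allowed <- matrix(TRUE, K + 2L, K + 2L, dimnames = list(names_all, names_all))
  cat_of <- ifelse(label_vocab == "O", NA, substring(label_vocab, 3L))
  is_i <- startsWith(label_vocab, "I-")
  for (from in seq_len(K + 1L)) {
    from_cat <- if (from <= K) cat_of[from] else NA  # START behaves like O
    for (to in seq_len(K)) {
      if (is_i[to] && (is.na(from_cat) || from_cat != cat_of[to])) {
        allowed[from, to] <- FALSE
      }
    }
  }
  allowed[, K + 1L] <- FALSE          # nothing enters START
  allowed[K + 2L, ] <- FALSE          # nothing leaves END
  allowed["START", "END"] <- FALSE    # empty path impossible
  allowed
}

#' Export a transition matrix (and optional mask) to JSON
#'
#' @param transitions `(K+2) x (K+2)` matrix.
#' @param label_vocab Label names for the first K states.
#' @param path Output path.
#' @param mask Optional logical mask to include.
#' @return `path`, invisibly.
#' @export
write_transitions_json <- function(transitions, label_vocab, path, mask = NULL) {
  obj <- list(labels = c(label_vocab, "START", "END"),
              scores = apply(transitions, 1, as.numeric, simplify = FALSE))
  if (!is.null(mask)) obj$allowed <- apply(mask, 1, as.logical, simplify = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
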