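# Seeded synthetic annotated corpora emulating a 4-type PHI corpus:
# dominant DAT type, rare LOC, variable entity density including
# entity-sparse sentences. Mentions are built from a closed synthetic
# alphabet (pseudo-tokens), never from real names or places.

#' Specification for the synthetic corpus generator
#'
#' Defaults emulate the structure of a de-identification training corpus:
#' entity-type proportions follow the original training-set composition
#' (PER .258, LOC .054, ORG .151, DAT .537), sentences vary in length, and a
#' fraction of sentences is entity-sparse (mostly `O` tokens).
#'
#' Each category draws mention tokens from its own sub-alphabet, but a share
#' of mention and background tokens comes from a shared ambiguous alphabet,
#' so type identity is not always decidable from a single token and the
#' tagger must use context.
#'
#' @param n_sentences Number of sentences.
#' @param len_range Inclusive sentence-length range in tokens.
#' @param entity_density Expected entities per (non-sparse) sentence.
#' @param proportions Named numeric over PER/LOC/ORG/DAT, summing to 1.
#' @param sparse_frac Fraction of entity-sparse sentences (density scaled by
#'   `sparse_density_factor`).
#' @param sparse_density_factor Density multiplier for sparse sentences.
#' @param background_vocab Background (O-token) alphabet size.
#' @param ambiguous_vocab Shared ambiguous alphabet size.
#' @param ambiguous_rate Probability that a mention token is drawn from the
#'   ambiguous alphabet.
#' @param seed Generator seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_sentences = 500L,
                           len_range = c(5L, 18L),
                           entity_density = 1.5,
                           proportions = c(PER = 0.258, LOC = 0.054,
                                           ORG = 0.151, DAT = 0.537),
                           sparse_frac = 0.3,
                           sparse_density_factor = 0.15,
                           background_vocab = 40L,
                           ambiguous_vocab = 10L,
                           ambiguous_rate = 0.3,
                           seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-6) stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (entity_density < 0) stop("entity_density must be >= 0")
  if (len_range[1] < 1 || len_range[2] < len_range[1]) stop("invalid len_range")
  # shortest mention is 2 tokens; a sentence must fit its entities
  max_ents <- floor(len_range[1] / 2)
  if (entity_density > max_ents) {
    stop(sprintf("entity density %.2f infeasible for minimum length %d",
                 entity_density, len_range[1]))
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 len_range = as.integer(len_range),
                 entity_density = entity_density,
                 proportions = proportions,
                 sparse_frac = sparse_frac,
                 sparse_density_factor = sparse_density_factor,
                 background_vocab = as.integer(background_vocab),
                 ambiguous_vocab = as.integer(ambiguous_vocab),
                 ambiguous_rate = ambiguous_rate,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# Per-category mention shape: alphabet prefix and token-length range.
# DAT mentions are longer and internally templated (digit-like sub-tokens
# with period separators) so type signal is learnable.
MENTION_SHAPES <- list(
  PER = list(prefix = "p", alphabet = 12L, len = c(2L, 3L)),
  LOC = list(prefix = "l", alphabet = 10L, len = c(2L, 4L)),
  ORG = list(prefix = "g", alphabet = 12L, len = c(3L, 5L)),
  DAT = list(prefix = "d", alphabet = 10L, len = c(4L, 7L))
)

synth_alphabet <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

sample_mention <- function(category, spec) {
  shape <- MENTION_SHAPES[[category]]
  len <- sample(shape$len[1]:shape$len[2], 1)
  amb <- synth_alphabet("a", spec$ambiguous_vocab)
  own <- synth_alphabet(shape$prefix, shape$alphabet)
  if (category == "DAT") {
    # templated: digit-like tokens with a period separator mid-mention
    toks <- sample(own, len, replace = TRUE)
    sep_at <- ceiling(len / 2)
    toks[sep_at] <- "sep"
    toks
  } else {
    from_amb <- stats::runif(len) < spec$ambiguous_rate
    ifelse(from_amb, sample(amb, len, replace = TRUE),
           sample(own, len, replace = TRUE))
  }
}

sample_background <- function(n, spec) {
  if (n == 0) return(character(0))
  bg <- synth_alphabet("c", spec$background_vocab)
  amb <- synth_alphabet("a", spec$ambiguous_vocab)
  from_amb <- stats::runif(n) < 0.15
  ifelse(from_amb, sample(amb, n, replace = TRUE),
         sample(bg, n, replace = TRUE))
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic per seed; every sentence is a valid BIO sequence and
#' realized entity-type fractions follow the spec's multinomial proportions.
#'
#' @param spec A [generator_spec()].
#' @return A `phi_corpus`.
#' @export
generate_corpus <- function(spec) {
  cats <- names(spec$proportions)
  sentences <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_sentences), function(i) {
      len <- sample(spec$len_range[1]:spec$len_range[2], 1)
      density <- spec$entity_density *
        if (stats::runif(1) < spec$sparse_frac) spec$sparse_density_factor else 1
      n_ent <- stats::rpois(1, density)
      mentions <- list()
      if (n_ent > 0) {
        types <- sample(cats, n_ent, replace = TRUE, prob = spec$proportions)
        mentions <- lapply(types, sample_mention, spec = spec)
        # drop entities that cannot fit
        while (length(mentions) > 0 &&
               sum(lengths(mentions)) > len) {
          mentions <- mentions[-length(mentions)]
          types <- types[-length(types)]
        }
      }
      n_bg <- len - if (length(mentions) > 0) sum(lengths(mentions)) else 0L
      tokens <- sample_background(n_bg, spec)
      tags <- rep("O", n_bg)
      if (length(mentions) > 0) {
        # insert mentions at random gap positions (entities may be adjacent)
        order_pos <- sort(sample.int(n_bg + 1L, length(mentions),
                                     replace = TRUE))
        for (k in rev(seq_along(mentions))) {
          m <- mentions[[k]]
          mt <- c(paste0("B-", types[k]),
                  rep(paste0("I-", types[k]), length(m) - 1L))
          at <- order_pos[k] - 1L
          tokens <- append(tokens, m, after = at)
          tags <- append(tags, mt, after = at)
        }
      }
      labeled_sentence(tokens, tags)
    })
  })
  phi_corpus(sentences, categories = cats)
}

#' Build surrogate replacement pools
#'
#' Surrogate mentions come from a dedicated alphabet (`s` prefix) that the
#' corpus generator never uses, so pools are guaranteed disjoint from gold
#' mentions.
#'
#' @param categories Category names.
#' @param size Mentions per category.
#' @param seed Seed.
#' @return Named list: per category, a list of character token vectors.
#' @export
make_surrogates <- function(categories = phi_categories(), size = 10L, seed) {
  with_seed(seed, {
    stats::setNames(lapply(categories, function(cat_i) {
      shape <- MENTION_SHAPES[[cat_i]]
      lens <- if (is.null(shape)) c(2L, 3L) else shape$len
      out <- list()
      tries <- 0L
      while (length(out) < size && tries < size * 50L) {
        tries <- tries + 1L
        len <- sample(lens[1]:lens[2], 1)
        m <- sprintf("s%02d", sample.int(30L, len, replace = TRUE))
        key <- paste(m, collapse = " ")
        if (!key %in% vapply(out, paste, character(1), collapse = " ")) {
          out[[length(out) + 1L]] <- m
        }
      }
      out
    }), categories)
  })
}

#' Write a generator manifest
#'
#' JSON record of the spec, seed and realized entity counts, written next to
#' emitted CoNLL files.
#'
#' @param spec A [generator_spec()].
#' @param corpus The generated `phi_corpus`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(spec, corpus, path) {
  jsonlite::write_json(
    list(spec = unclass(spec),
         realized_entity_counts = as.list(corpus_entity_counts(corpus)),
         n_sentences = length(corpus$sentences)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
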