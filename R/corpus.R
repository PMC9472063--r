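#' @keywords internal
"_PACKAGE"

# PHI categories form a closed set; extension requires passing `categories`
# explicitly to the functions that accept it.
PHI_CATEGORIES <- c("PER", "LOC", "ORG", "DAT")

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' PHI categories
#'
#' The four protected-health-information entity categories handled by default:
#' personal names (PER), locations (LOC), organizations (ORG) and dates (DAT).
#'
#' @return Character vector of category names.
#' @export
phi_categories <- function() PHI_CATEGORIES

#' Build the BIO label vocabulary for a category set
#'
#' @param categories Character vector of entity categories.
#' @return Character vector: `"O"` followed by `B-`/`I-` labels per category.
#' @export
bio_label_vocab <- function(categories = phi_categories()) {
  stopifnot(length(categories) >= 1, !anyDuplicated(categories))
  c("O", as.vector(rbind(paste0("B-", categories), paste0("I-", categories))))
}

#' Construct an entity-span table
#'
#' Spans are 0-based, half-open `[start, end)` in token units, typed by
#' category, sorted by start, and pairwise non-overlapping.
#'
#' @param start,end Integer vectors (same length), `0 <= start < end`.
#' @param category Character vector of categories.
#' @return A `data.frame` with columns `start`, `end`, `category`.
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         category = character()) {
  stopifnot(length(start) == length(end), length(end) == length(category))
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$start < 0) || any(df$end <= df$start)) {
      stop("invalid span: need 0 <= start < end")
    }
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
      bad <- which(df$start[-1] < df$end[-nrow(df)])[1]
      stop(sprintf("overlapping spans: (%d,%d,%s) and (%d,%d,%s)",
                   df$start[bad], df$end[bad], df$category[bad],
                   df$start[bad + 1], df$end[bad + 1], df$category[bad + 1]))
    }
  }
  df
}

#' Construct a labeled sentence
#'
#' A sentence is a sequence of surface units (characters in character mode,
#' whitespace tokens otherwise) with one BIO tag per unit. Entity spans are
#' derived from the tags, never stored independently.
#'
#' @param tokens Character vector of surface units.
#' @param tags Character vector of BIO tags, same length as `tokens`.
#' @param source Provenance label (e.g. `"original"`, `"daga"`, `"mr"`).
#' @return An object of class `labeled_sentence`.
#' @export
labeled_sentence <- function(tokens, tags = rep("O", length(tokens)),
                             source = "original") {
  tokens <- as.character(tokens)
  tags <- as.character(tags)
  if (length(tokens) != length(tags)) {
    stop(sprintf("length mismatch: %d tokens vs %d tags",
                 length(tokens), length(tags)))
  }
  v <- validate_bio(tags)
  if (length(v) > 0) {
    stop(sprintf("invalid BIO sequence: %s", format_violation(v[[1]])))
  }
  structure(list(tokens = tokens, tags = tags, source = source),
            class = "labeled_sentence")
}

#' @export
print.labeled_sentence <- function(x, ...) {
  cat(sprintf("<labeled_sentence> %d tokens, %d entities [%s]\n",
              length(x$tokens), nrow(sentence_entities(x)), x$source))
  cat(paste(x$tokens, collapse = " "), "\n")
  cat(paste(x$tags, collapse = " "), "\n")
  invisible(x)
}

#' Entity spans of a labeled sentence
#'
#' @param sentence A `labeled_sentence`.
#' @return Span `data.frame` as from [entity_spans()].
#' @export
sentence_entities <- function(sentence) {
  bio_to_spans(sentence$tags)
}

#' Expand entity spans to a BIO tag sequence
#'
#' The first token of each span receives `B-<cat>`, subsequent tokens
#' `I-<cat>`, and all uncovered tokens `O`.
#'
#' @param length Sentence length in tokens.
#' @param spans Span table from [entity_spans()].
#' @return Character vector of BIO tags of the given length.
#' @export
spans_to_bio <- function(length, spans) {
  length <- as.integer(length)
  spans <- entity_spans(spans$start, spans$end, spans$category)
  tags <- rep("O", length)
  if (nrow(spans) > 0 && max(spans$end) > length) {
    bad <- spans[which(spans$end > length)[1], ]
    stop(sprintf("span (%d,%d,%s) exceeds sentence length %d",
                 bad$start, bad$end, bad$category, length))
  }
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i] + 1L
    e <- spans$end[i]
    tags[s] <- paste0("B-", spans$category[i])
    if (e > s) tags[(s + 1L):e] <- paste0("I-", spans$category[i])
  }
  tags
}

#' Recover entity spans from a BIO tag sequence
#'
#' Exact inverse of [spans_to_bio()] on valid sequences.
#'
#' @param tags Character vector of BIO tags.
#' @return Span `data.frame`.
#' @export
bio_to_spans <- function(tags) {
  v <- validate_bio(tags)
  if (length(v) > 0) {
    stop(sprintf("invalid BIO sequence: %s", format_violation(v[[1]])))
  }
  start <- integer(); end <- integer(); category <- character()
  open_start <- NA_integer_; open_cat <- NA_character_
  close_open <- function(i) {
    if (!is.na(open_start)) {
      start <<- c(start, open_start - 1L)   # to 0-based
      end <<- c(end, i - 1L)                # exclusive
      category <<- c(category, open_cat)
      open_start <<- NA_integer_
    }
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      close_open(i)
    } else if (startsWith(t, "B-")) {
      close_open(i)
      open_start <- i
      open_cat <- substring(t, 3L)
    }
    # I- continues the open span; validity guaranteed by validate_bio
  }
  close_open(length(tags) + 1L)
  entity_spans(start, end, category)
}

#' Validate a BIO tag sequence
#'
#' Checks the tag-dependency rules: a sentence may not open with `I-`, `I-`
#' may not follow `O`, and an `I-` tag must carry the same category as the
#' tag it continues (excluding e.g. `B-PER I-ORG`). Unknown tag strings are
#' also reported.
#'
#' @param tags Character vector of candidate tags.
#' @return A list of violations (empty iff valid); each violation is a list
#'   with `position` (1-based) and `rule` (one of `"unknown-tag"`,
#'   `"sentence-initial-I"`, `"I-after-O"`, `"category-switch"`).
#' @export
validate_bio <- function(tags) {
  violations <- list()
  add <- function(pos, rule) {
    violations[[length(violations) + 1L]] <<- list(position = pos, rule = rule)
  }
  prev_cat <- NA_character_  # category continuable at this point, NA if none
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      prev_cat <- NA_character_
    } else if (grepl("^B-.+$", t)) {
      prev_cat <- substring(t, 3L)
    } else if (grepl("^I-.+$", t)) {
      cat_i <- substring(t, 3L)
      if (i == 1L) {
        add(i, "sentence-initial-I")
      } else if (is.na(prev_cat)) {
        add(i, "I-after-O")
      } else if (cat_i != prev_cat) {
        add(i, "category-switch")
      }
      prev_cat <- cat_i
    } else {
      add(i, "unknown-tag")
      prev_cat <- NA_character_
    }
  }
  violations
}

format_violation <- function(v) {
  msg <- switch(v$rule,
    "sentence-initial-I" = "sentence-initial I- tag",
    "I-after-O" = "I- tag after O",
    "category-switch" = "category mismatch",
    "unknown-tag" = "unknown tag")
  sprintf("%s at position %d", msg, v$position - 1L)
}

#' Construct a corpus
#'
#' A corpus is a list of labeled sentences plus stable label and token
#' vocabularies. The token vocabulary reserves `<pad>` and `<unk>` at the
#' first two indices; vocabulary order is preserved across save/load.
#'
#' @param sentences List of `labeled_sentence` objects.
#' @param categories Entity category set (defaults to the PHI four).
#' @param token_vocab Optional explicit token vocabulary; built from the
#'   sentences when `NULL`.
#' @return An object of class `phi_corpus`.
#' @export
phi_corpus <- function(sentences, categories = phi_categories(),
                       token_vocab = NULL) {
  stopifnot(is.list(sentences))
  for (s in sentences) {
    if (!inherits(s, "labeled_sentence")) stop("sentences must be labeled_sentence objects")
  }
  label_vocab <- bio_label_vocab(categories)
  seen <- unique(unlist(lapply(sentences, `[[`, "tags")))
  extra <- setdiff(seen, label_vocab)
  if (length(extra) > 0) {
    stop(sprintf("tags outside label vocabulary: %s",
                 paste(extra, collapse = ", ")))
  }
  if (is.null(token_vocab)) {
    toks <- unique(unlist(lapply(sentences, `[[`, "tokens")))
    token_vocab <- c(PAD_TOKEN, UNK_TOKEN, sort(setdiff(toks, c(PAD_TOKEN, UNK_TOKEN))))
  } else {
    if (!identical(token_vocab[1:2], c(PAD_TOKEN, UNK_TOKEN))) {
      stop("token_vocab must reserve <pad>, <unk> at indices 1, 2")
    }
  }
  structure(list(sentences = sentences, label_vocab = label_vocab,
                 token_vocab = token_vocab, categories = categories),
            class = "phi_corpus")
}

#' @export
print.phi_corpus <- function(x, ...) {
  ents <- corpus_entity_counts(x)
  cat(sprintf("<phi_corpus> %d sentences, %d tokens in vocab, %d labels\n",
              length(x$sentences), length(x$token_vocab), length(x$label_vocab)))
  cat("entities:", paste(sprintf("%s=%d", names(ents), ents), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.phi_corpus <- function(x) length(x$sentences)

#' Per-category entity counts of a corpus
#'
#' @param corpus A `phi_corpus`.
#' @return Named integer vector over the corpus categories.
#' @export
corpus_entity_counts <- function(corpus) {
  counts <- stats::setNames(integer(length(corpus$categories)), corpus$categories)
  for (s in corpus$sentences) {
    sp <- sentence_entities(s)
    if (nrow(sp) > 0) {
      tab <- table(factor(sp$category, levels = corpus$categories))
      counts <- counts + as.integer(tab)
    }
  }
  counts
}

#' Read a CoNLL-style two-column corpus
#'
#' Lines hold `token<TAB>tag` (any whitespace accepted as the delimiter);
#' blank lines separate sentences. Malformed lines are reported with their
#' line numbers.
#'
#' @param path File path or connection.
#' @param categories Entity category set.
#' @param on_invalid How to handle sentences with invalid BIO tags:
#'   `"error"` (default) rejects with position and rule; `"repair"` rewrites
#'   offending tags to `"O"`.
#' @return A `phi_corpus`.
#' @export
read_conll <- function(path, categories = phi_categories(),
                       on_invalid = c("error", "repair")) {
  on_invalid <- match.arg(on_invalid)
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- list()
  toks <- character(); tags <- character()
  flush_sentence <- function(line_no) {
    if (length(toks) == 0) return()
    v <- validate_bio(tags)
    if (length(v) > 0) {
      if (on_invalid == "error") {
        stop(sprintf("invalid BIO in sentence ending before line %d: %s",
                     line_no, format_violation(v[[1]])))
      }
      for (viol in v) tags[viol$position] <<- "O"
    }
    sentences[[length(sentences) + 1L]] <<- labeled_sentence(toks, tags)
    toks <<- character(); tags <<- character()
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^\\s*$", line)) {
      flush_sentence(i)
      next
    }
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("line %d: expected 2 columns, got %d", i, length(parts)))
    }
    toks <- c(toks, parts[1]); tags <- c(tags, parts[2])
  }
  flush_sentence(length(lines) + 1L)
  phi_corpus(sentences, categories = categories)
}

#' Write a corpus in CoNLL-style two-column form
#'
#' @param corpus A `phi_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  blocks <- vapply(corpus$sentences, function(s) {
    paste0(paste(s$tokens, s$tags, sep = "\t", collapse = "\n"), "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Deterministically split a corpus into train/eval/test
#'
#' Sentences are permuted with the given seed and cut at the ratio
#' boundaries; part sizes are within one sentence of `ratio * N`.
#'
#' @param corpus A `phi_corpus`.
#' @param ratios Numeric vector of three positive weights (normalized to 1);
#'   default 6:2:2.
#' @param seed Integer seed controlling the permutation.
#' @return Named list `train`, `eval`, `test` of `phi_corpus` objects; the
#'   three parts share the parent corpus vocabularies.
#' @export
split_corpus <- function(corpus, ratios = c(0.6, 0.2, 0.2), seed) {
  stopifnot(length(ratios) == 3)
  if (any(ratios <= 0)) stop("all split ratios must be positive")
  ratios <- ratios / sum(ratios)
  n <- length(corpus$sentences)
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(ratios[1] * n)
  n_eval <- round(ratios[2] * n)
  n_train <- min(n_train, n)
  n_eval <- min(n_eval, n - n_train)
  idx <- list(train = perm[seq_len(n_train)],
              eval = if (n_eval > 0) perm[n_train + seq_len(n_eval)] else integer(),
              test = if (n - n_train - n_eval > 0) perm[(n_train + n_eval + 1L):n] else integer())
  if (any(vapply(idx, length, integer(1)) == 0)) {
    warning("degenerate split: at least one part is empty")
  }
  lapply(idx, function(ii) {
    phi_corpus(corpus$sentences[ii], categories = corpus$categories,
               token_vocab = corpus$token_vocab)
  })
}

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Persist corpus vocabularies as JSON
#'
#' @param corpus A `phi_corpus`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_vocab_json <- function(corpus, path) {
  jsonlite::write_json(
    list(label_vocab = corpus$label_vocab, token_vocab = corpus$token_vocab,
         categories = corpus$categories),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
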