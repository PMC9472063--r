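# Entity-level evaluation: exact span+type matching, per-category and
# pooled (micro) precision/recall/F1 in percent.

#' Match predicted entities against gold entities
#'
#' A predicted span is a true positive iff a gold span in the same sentence
#' has identical (start, end, category); no partial credit. Unmatched
#' predictions are false positives, unmatched gold spans false negatives.
#'
#' @param gold,pred `phi_corpus` objects over the same sentences (same
#'   count, same token sequences).
#' @return A `data.frame` with one row per category: `category`, `tp`, `fp`,
#'   `fn`.
#' @export
match_entities <- function(gold, pred) {
  if (length(gold$sentences) != length(pred$sentences)) {
    stop("gold and prediction have different sentence counts")
  }
  cats <- gold$categories
  tp <- stats::setNames(integer(length(cats)), cats)
  fp <- tp; fn <- tp
  for (i in seq_along(gold$sentences)) {
    g <- gold$sentences[[i]]; p <- pred$sentences[[i]]
    if (length(g$tokens) != length(p$tokens)) {
      stop(sprintf("sentence %d: token length mismatch (%d vs %d)",
                   i, length(g$tokens), length(p$tokens)))
    }
    gs <- sentence_entities(g); ps <- sentence_entities(p)
    gkey <- sprintf("%d:%d:%s", gs$start, gs$end, gs$category)
    pkey <- sprintf("%d:%d:%s", ps$start, ps$end, ps$category)
    hit <- pkey %in% gkey
    for (k in seq_len(nrow(ps))) {
      if (hit[k]) tp[ps$category[k]] <- tp[ps$category[k]] + 1L
      else fp[ps$category[k]] <- fp[ps$category[k]] + 1L
    }
    miss <- !(gkey %in% pkey)
    for (k in seq_len(nrow(gs))) {
      if (miss[k]) fn[gs$category[k]] <- fn[gs$category[k]] + 1L
    }
  }
  data.frame(category = cats, tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), stringsAsFactors = FALSE)
}

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = 100 * p, recall = 100 * r, f1 = 100 * f1)
}

#' Precision / recall / F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, reported in percent.
#' Micro metrics are computed from the pooled counts. Zero denominators give
#' 0 by convention.
#'
#' @param counts Count table from [match_entities()], or a single-row list /
#'   data.frame with `tp`, `fp`, `fn`.
#' @return An object of class `eval_report`: list with `per_category`
#'   (`data.frame` of category, tp, fp, fn, precision, recall, f1) and
#'   `micro` (named vector precision/recall/f1 in percent) plus pooled
#'   `counts`.
#' @export
score_entities <- function(counts) {
  counts <- as.data.frame(counts)
  if (!all(c("tp", "fp", "fn") %in% names(counts))) {
    stop("counts must have tp, fp, fn columns")
  }
  if (is.null(counts$category)) counts$category <- "all"
  per <- cbind(counts,
               t(mapply(prf, counts$tp, counts$fp, counts$fn)))
  pooled <- c(tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn))
  micro <- prf(pooled["tp"], pooled["fp"], pooled["fn"])
  structure(list(per_category = per, micro = micro, counts = pooled),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Entity-level evaluation (exact span + type match)\n")
  df <- x$per_category
  df$precision <- sprintf("%.2f", df$precision)
  df$recall <- sprintf("%.2f", df$recall)
  df$f1 <- sprintf("%.2f", df$f1)
  print(df, row.names = FALSE)
  cat(sprintf("micro: P %.2f  R %.2f  F1 %.2f  (TP %d FP %d FN %d)\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"],
              x$counts["tp"], x$counts["fp"], x$counts["fn"]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(
    list(per_category = report$per_category,
         micro = as.list(report$micro),
         counts = as.list(report$counts)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
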