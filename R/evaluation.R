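# Entity-level evaluation: strict exact-boundary, exact-type matching of
# mentions (TP/FP/FN), precision/recall/F1 with total zero-denominator
# conventions, pairwise token-level output difference, and McNemar's test
# on span-level labeling disagreements.

mention_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(m$doc_id, m$sentence_index, m$start_token, m$end_token,
        m$entity_type, sep = "\r")
}

#' Match predicted against gold mentions
#'
#' A true positive is an exact match on (document, sentence, start token,
#' end token, entity type); unmatched predictions are false positives and
#' unmatched gold mentions false negatives. Gold should include any
#' untrainable sub-token mentions so they count as errors.
#'
#' @param gold,predicted mention data.frames.
#' @return list with integer fields `tp`, `fp`, `fn`.
#' @export
match_entities <- function(gold, predicted) {
  gk <- mention_keys(gold)
  pk <- mention_keys(predicted)
  tp <- sum(pk %in% gk)
  list(tp = as.integer(tp), fp = as.integer(length(pk) - tp),
       fn = as.integer(length(gk) - tp))
}

#' Precision, recall and F1 from match counts
#'
#' R = TP/(TP+FN), P = TP/(TP+FP), F1 = 2PR/(P+R). A zero denominator
#' yields 0 for the affected metric (and F1 = 0 when P+R = 0), keeping
#' the function total.
#'
#' @param counts list with `tp`, `fp`, `fn` (from [match_entities()]).
#' @return list with `precision`, `recall`, `f1` and the counts.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = p, recall = r, f1 = f_score(p, r),
       tp = tp, fp = fp, fn = fn)
}

#' Harmonic mean of precision and recall
#' @param p,r precision and recall in [0, 1].
#' @return F1, with the convention F1 = 0 when `p + r == 0`.
#' @export
f_score <- function(p, r) {
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Entity-level metrics report, optionally per type
#'
#' @param gold,predicted mention data.frames.
#' @param per_type also break metrics down by entity type.
#' @return a `metrics_report`: list with `overall` and (if requested)
#'   `per_type` (named list over the union of observed types).
#' @export
evaluate_mentions <- function(gold, predicted, per_type = FALSE) {
  out <- list(overall = compute_metrics(match_entities(gold, predicted)))
  if (per_type) {
    types <- sort(unique(c(gold$entity_type, predicted$entity_type)))
    out$per_type <- setNames(lapply(types, function(ty) {
      compute_metrics(match_entities(
        gold[gold$entity_type == ty, , drop = FALSE],
        predicted[predicted$entity_type == ty, , drop = FALSE]))
    }), types)
  }
  structure(out, class = "metrics_report")
}

#' Score a predicted tagging against a corpus's gold labels
#'
#' @param corpus gold `ner_corpus`.
#' @param tags predicted tagging (list of tag vectors in corpus order).
#' @param per_type break down by entity type.
#' @param extra_gold optional additional gold mentions (e.g. untrainable
#'   sub-token mentions) appended to the gold standard; token-indexed
#'   rows are matched as usual, rows that no tagging can produce simply
#'   count as false negatives.
#' @return a `metrics_report`.
#' @export
evaluate_tags <- function(corpus, tags, per_type = FALSE,
                          extra_gold = NULL) {
  gold <- corpus_mentions(corpus)
  if (!is.null(extra_gold) && nrow(extra_gold) > 0L) {
    keep <- intersect(names(gold), names(extra_gold))
    ex <- extra_gold
    for (nm in setdiff(names(gold), names(ex))) ex[[nm]] <- NA
    gold <- rbind(gold, ex[, names(gold), drop = FALSE])
  }
  evaluate_mentions(gold, tags_to_mentions(corpus, tags), per_type)
}

#' @export
print.metrics_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("P %.2f  R %.2f  F1 %.2f  (tp %d, fp %d, fn %d)\n",
              round_half_up(o$precision), round_half_up(o$recall),
              round_half_up(o$f1), o$tp, o$fp, o$fn))
  if (!is.null(x$per_type)) {
    for (ty in names(x$per_type)) {
      m <- x$per_type[[ty]]
      cat(sprintf("  %-14s P %.2f  R %.2f  F1 %.2f\n", ty,
                  round_half_up(m$precision), round_half_up(m$recall),
                  round_half_up(m$f1)))
    }
  }
  invisible(x)
}

#' Percentage of token positions on which two taggings differ
#'
#' @param tags_a,tags_b token-aligned taggings (lists of tag vectors, or
#'   plain character vectors).
#' @return percentage in [0, 100].
#' @export
pairwise_difference <- function(tags_a, tags_b) {
  a <- unlist(tags_a); b <- unlist(tags_b)
  if (length(a) != length(b)) {
    stop_crf("taggings are not token-aligned (%d vs %d tokens)",
             length(a), length(b), class = "crfvoter_alignment")
  }
  100 * sum(a != b) / length(a)
}

# is `tags` exactly the gold labeling over the mention's span, including
# the B-/I- pattern?
span_correct <- function(mention, gold_tags, sys_tags) {
  idx <- (mention$start_token + 1L):mention$end_token
  identical(sys_tags[idx], gold_tags[idx])
}

#' McNemar's test on span-level labeling disagreements
#'
#' For every gold mention, a system is "positive" when its predicted tags
#' over the mention's token span exactly reproduce the gold tags. `b`
#' counts mentions only system 1 gets right, `c` those only system 2 gets
#' right. The continuity-corrected statistic is
#' `(|b - c| - 1)^2 / (b + c)`, referred to the chi-square(1) critical
#' value at `alpha`; `exact = TRUE` uses the binomial sign test instead.
#'
#' @param corpus gold `ner_corpus`.
#' @param tags1,tags2 token-aligned predicted taggings.
#' @param alpha significance level in (0, 1).
#' @param exact use the exact binomial variant.
#' @return list with `b`, `c`, `statistic` (or `p_value` when exact),
#'   `significant`, `undefined` (TRUE when b + c = 0).
#' @export
mcnemar_test <- function(corpus, tags1, tags2, alpha = 0.05,
                         exact = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  b <- 0L; cc <- 0L
  k <- 0L
  for (doc in corpus$documents) {
    for (si in seq_along(doc$sentences)) {
      k <- k + 1L
      s <- doc$sentences[[si]]
      mentions <- iob_to_spans(s$labels, doc$doc_id, si - 1L)
      for (mi in seq_len(nrow(mentions))) {
        m <- mentions[mi, , drop = FALSE]
        ok1 <- span_correct(m, s$labels, tags1[[k]])
        ok2 <- span_correct(m, s$labels, tags2[[k]])
        if (ok1 && !ok2) b <- b + 1L
        if (ok2 && !ok1) cc <- cc + 1L
      }
    }
  }
  mcnemar_from_counts(b, cc, alpha, exact)
}

#' McNemar decision from discordant counts
#' @param b,c discordant counts.
#' @inheritParams mcnemar_test
#' @return same structure as [mcnemar_test()].
#' @export
mcnemar_from_counts <- function(b, c, alpha = 0.05, exact = FALSE) {
  stopifnot(b >= 0, c >= 0, alpha > 0, alpha < 1)
  if (b + c == 0) {
    return(list(b = b, c = c, statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, undefined = TRUE))
  }
  if (exact) {
    p <- min(1, 2 * pbinom(min(b, c), b + c, 0.5))
    return(list(b = b, c = c, statistic = NA_real_, p_value = p,
                significant = p < alpha, undefined = FALSE))
  }
  stat <- (abs(b - c) - 1)^2 / (b + c)
  list(b = b, c = c, statistic = stat, p_value = NA_real_,
       significant = stat > qchisq(1 - alpha, df = 1),
       undefined = FALSE)
}
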