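# Ensembles of base sequence labelers: a positionwise majority-vote
# baseline and the two-stage stacked CRF in which each base learner's
# output label at position j becomes an input feature of a second-level
# linear-chain CRF trained on a development set disjoint from the bases'
# training data (training the combiner on the bases' own training
# predictions would leak optimistic base accuracy).

#' CRF base learner specification
#'
#' A trainable base learner: a feature template (fixed or searched over a
#' parameter space) plus CRF penalty settings.
#'
#' @param learner_id unique identifier.
#' @param config a [feature_config()] used when no space is given.
#' @param penalty,cost_c CRF training settings.
#' @param space optional [param_space()] over feature switches/knobs and
#'   optionally `penalty`/`cost_c`, searched during stage-1 optimization.
#' @param budget,method hyperparameter search budget and method
#'   (`"random"` or `"tpe"`) when `space` is given.
#' @param gaz optional gazetteer.
#' @param max_iter CRF training iteration cap.
#' @return a `crf_learner` object.
#' @export
crf_learner <- function(learner_id, config = feature_config(use_word = TRUE),
                        penalty = "L2", cost_c = 15, space = NULL,
                        budget = 10L, method = "tpe", gaz = NULL,
                        max_iter = 150L) {
  structure(list(learner_id = learner_id, config = config,
                 penalty = penalty, cost_c = cost_c, space = space,
                 budget = budget, method = method, gaz = gaz,
                 max_iter = max_iter, model = NULL),
            class = "crf_learner")
}

#' Simulated base learner backed by an error profile
#'
#' A test double for an external sequence labeler: its predictions are
#' the corpus gold labels corrupted by the profile's deletion, jitter and
#' confusion rates (see [simulate_learner_output()]). It requires no
#' training and is deterministic given the profile seed.
#'
#' @param profile an [error_profile()].
#' @return a `simulated_learner` object.
#' @export
simulated_learner <- function(profile) {
  structure(list(learner_id = profile$learner_id, profile = profile),
            class = "simulated_learner")
}

corpus_instances <- function(corpus, config, gaz = NULL) {
  lapply(corpus_sentences(corpus), function(s)
    list(features = sentence_features(s, config, gaz), labels = s$labels))
}

#' Train a base learner (stage 1)
#'
#' With a parameter space attached, hyper-optimizes the feature template
#' (and optionally penalty settings) by maximizing dev-set F1; otherwise
#' trains directly with the fixed configuration.
#'
#' @param learner a `crf_learner` or `simulated_learner`.
#' @param train,dev corpora.
#' @param seed integer seed for the search.
#' @return the learner with a trained `model` (simulated learners pass
#'   through unchanged).
#' @export
train_learner <- function(learner, train, dev, seed = 1L) {
  UseMethod("train_learner")
}

#' @export
train_learner.simulated_learner <- function(learner, train, dev, seed = 1L) {
  learner
}

config_from_assignment <- function(assignment) {
  knobs <- intersect(names(assignment),
                     c("max_left", "max_right", "max_ngram_leng",
                       "word_shape", "tag_column", "lemma_column"))
  switches <- assignment[intersect(names(assignment), .fc_switches)]
  do.call(feature_config, c(switches, assignment[knobs]))
}

#' @export
train_learner.crf_learner <- function(learner, train, dev, seed = 1L) {
  fit <- function(config, penalty, cost_c) {
    crf_train(corpus_instances(train, config, learner$gaz),
              penalty = penalty, cost_c = cost_c,
              max_iter = learner$max_iter)
  }
  if (is.null(learner$space)) {
    learner$model <- fit(learner$config, learner$penalty, learner$cost_c)
    return(learner)
  }
  objective <- function(cfg) {
    config <- config_from_assignment(cfg)
    penalty <- if ("a" %in% names(cfg)) {
      if (identical(cfg$a, "CRF-L1")) "L1" else "L2"
    } else learner$penalty
    cost_c <- cfg$c %||% learner$cost_c
    model <- fit(config, penalty, cost_c)
    tags <- lapply(corpus_sentences(dev), function(s)
      viterbi_decode(model, sentence_features(s, config, learner$gaz)))
    evaluate_tags(dev, tags)$overall$f1
  }
  rep <- optimize_params(learner$space, objective, method = learner$method,
                         budget = learner$budget, seed = seed)
  best <- rep$best$config
  learner$config <- config_from_assignment(best)
  if ("a" %in% names(best)) {
    learner$penalty <- if (identical(best$a, "CRF-L1")) "L1" else "L2"
  }
  learner$cost_c <- best$c %||% learner$cost_c
  learner$model <- fit(learner$config, learner$penalty, learner$cost_c)
  learner$report <- rep
  learner
}

#' Predict tags for a corpus with a base learner
#' @param learner a trained base learner.
#' @param corpus an `ner_corpus`.
#' @return list of tag vectors in corpus order.
#' @export
predict_learner <- function(learner, corpus) {
  UseMethod("predict_learner")
}

#' @export
predict_learner.simulated_learner <- function(learner, corpus) {
  simulate_learner_output(corpus, learner$profile)
}

#' @export
predict_learner.crf_learner <- function(learner, corpus) {
  if (is.null(learner$model)) {
    stop_crf("base learner '%s' is untrained", learner$learner_id,
             class = "crfvoter_state")
  }
  lapply(corpus_sentences(corpus), function(s)
    suppressWarnings(repair_iob(
      viterbi_decode(learner$model,
                     sentence_features(s, learner$config, learner$gaz)))))
}

#' Positionwise majority vote over base outputs
#'
#' Per token position the modal tag wins. Ties are broken by learner
#' priority (`tie = "priority"`: among the tied tags, the one emitted by
#' the earliest-listed learner) or toward `"O"` (`tie = "prefer_o"`,
#' falling back to priority when "O" is not among the tied tags). The
#' voted sequence is repaired to valid IOB2.
#'
#' @param taggings list of l predicted taggings (each a list of tag
#'   vectors of identical shape).
#' @param tie `"priority"` or `"prefer_o"`.
#' @return voted tagging (list of tag vectors).
#' @export
majority_vote <- function(taggings, tie = c("priority", "prefer_o")) {
  tie <- match.arg(tie)
  stopifnot(length(taggings) >= 1L)
  n_sent <- unique(lengths(taggings))
  if (length(n_sent) != 1L) {
    stop_crf("taggings disagree on sentence count",
             class = "crfvoter_alignment")
  }
  lapply(seq_len(n_sent), function(k) {
    sent_tags <- lapply(taggings, `[[`, k)
    if (length(unique(lengths(sent_tags))) != 1L) {
      stop_crf("taggings disagree on sentence length",
               class = "crfvoter_alignment")
    }
    mat <- do.call(cbind, sent_tags)
    voted <- vapply(seq_len(nrow(mat)), function(j) {
      tags <- mat[j, ]
      counts <- table(tags)
      winners <- names(counts)[counts == max(counts)]
      if (length(winners) == 1L) return(winners)
      if (tie == "prefer_o" && "O" %in% winners) return("O")
      tags[which(tags %in% winners)[1]]
    }, character(1))
    suppressWarnings(repair_iob(voted))
  })
}

#' Stacked feature rows from base outputs
#'
#' Row j holds one feature `"<learner_id>=<tag>"` per base learner (the
#' learner's output label at position j); with `window > 0`, the base
#' outputs at positions j+/-1..j+/-w are added with positional prefixes
#' (boundary sentinels outside the sentence).
#'
#' @param base_tags named list mapping learner_id to that learner's tag
#'   vector for one sentence (equal lengths).
#' @param window stacking context width (default 0: position j only).
#' @return list of character feature vectors, one per position.
#' @export
build_stacked_rows <- function(base_tags, window = 0L) {
  lens <- unique(lengths(base_tags))
  if (length(lens) != 1L) {
    stop_crf("base outputs disagree on sentence length",
             class = "crfvoter_alignment")
  }
  n <- lens
  ids <- names(base_tags)
  lapply(seq_len(n), function(j) {
    row <- vapply(ids, function(id) paste0(id, "=", base_tags[[id]][j]),
                  character(1))
    if (window > 0L) for (w in seq_len(window)) {
      for (id in ids) {
        row <- c(row,
                 paste0(id, "@-", w, "=", .ctx(base_tags[[id]], j, -w)),
                 paste0(id, "@+", w, "=", .ctx(base_tags[[id]], j, w)))
      }
    }
    c("b", unname(row))
  })
}

stacked_instances <- function(learners, corpus, window,
                              gold = TRUE) {
  ids <- vapply(learners, `[[`, character(1), "learner_id")
  preds <- lapply(learners, predict_learner, corpus = corpus)
  names(preds) <- ids
  sents <- corpus_sentences(corpus)
  lapply(seq_along(sents), function(k) {
    base_tags <- setNames(lapply(preds, `[[`, k), ids)
    inst <- list(features = build_stacked_rows(base_tags, window))
    if (gold) inst$labels <- sents[[k]]$labels
    inst
  })
}

#' Train the two-stage stacked CRF ensemble
#'
#' Stage 1 trains (and, where a space is attached, hyper-optimizes) each
#' base learner on `train`. Stage 2 has every base tag the development
#' set and trains the second-level CRF on the resulting stacked rows
#' against the development gold labels. `train` and `dev` must be
#' disjoint at document level.
#'
#' @param train,dev corpora (disjoint document sets).
#' @param learners list of `crf_learner` / `simulated_learner` objects
#'   with unique ids.
#' @param level2_penalty,level2_c penalty settings of the combiner CRF.
#' @param window stacking context width (default 0).
#' @param seed master seed (fanned out per base learner).
#' @return a `crfvoter_model`.
#' @export
train_crfvoter <- function(train, dev, learners, level2_penalty = "L2",
                           level2_c = 15, window = 0L, seed = 1L) {
  if (length(dev$documents) == 0L) {
    stop_crf("empty development set", class = "crfvoter_insufficient_data")
  }
  ids <- vapply(learners, `[[`, character(1), "learner_id")
  if (anyDuplicated(ids)) {
    stop_crf("learner ids must be unique", class = "crfvoter_config")
  }
  overlap <- intersect(
    vapply(train$documents, `[[`, character(1), "doc_id"),
    vapply(dev$documents, `[[`, character(1), "doc_id"))
  if (length(overlap)) {
    stop_crf("train and dev share document(s): %s",
             paste(head(overlap, 3), collapse = ", "),
             class = "crfvoter_leakage")
  }
  learners <- lapply(seq_along(learners), function(i)
    train_learner(learners[[i]], train, dev, seed = derive_seed(seed, i)))
  gold_labels <- unique(unlist(corpus_labels(dev)))
  label_set <- c("O", sort(setdiff(gold_labels, "O")))
  level2 <- crf_train(stacked_instances(learners, dev, window),
                      penalty = level2_penalty, cost_c = level2_c,
                      labels = label_set)
  structure(list(learners = learners, level2 = level2, window = window,
                 seed = seed),
            class = "crfvoter_model")
}

#' Tag a corpus with a trained stacked ensemble
#'
#' Runs every base learner, builds the stacked rows and Viterbi-decodes
#' the second-level CRF; output is repaired to valid IOB2.
#'
#' @param object a `crfvoter_model`.
#' @param corpus an `ner_corpus`.
#' @param ... unused.
#' @return list of tag vectors in corpus order.
#' @export
predict.crfvoter_model <- function(object, corpus, ...) {
  if (length(corpus$documents) == 0L) return(list())
  insts <- stacked_instances(object$learners, corpus, object$window,
                             gold = FALSE)
  lapply(insts, function(inst)
    suppressWarnings(repair_iob(
      viterbi_decode(object$level2, inst$features))))
}

#' @export
print.crfvoter_model <- function(x, ...) {
  cat(sprintf("<crfvoter_model: %d base learners, window %d>\n",
              length(x$learners), x$window))
  invisible(x)
}
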