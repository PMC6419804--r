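# Shared fixtures: small random corpora and independent brute-force
# oracles for the CRF and the entity scorer. Everything here is built in
# code at test time under explicit seeds.

rand_word <- function(n = 1L, min_len = 2L, max_len = 7L) {
  vapply(seq_len(n), function(i)
    paste(sample(letters, sample(min_len:max_len, 1L), replace = TRUE),
          collapse = ""), character(1))
}

# random corpus built directly (independent of the generator module)
random_test_corpus <- function(seed, n_docs = 3L, types = c("X", "Y"),
                               with_columns = FALSE) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    docs <- lapply(seq_len(n_docs), function(d) {
      sents <- lapply(seq_len(sample(1:3, 1L)), function(s) {
        n <- sample(3:9, 1L)
        toks <- rand_word(n)
        labels <- rep("O", n)
        if (runif(1) < 0.8) {
          len <- sample(1:2, 1L)
          st <- sample(seq_len(n - len + 1L), 1L)
          ty <- sample(types, 1L)
          labels[st] <- paste0("B-", ty)
          if (len > 1L) labels[st + 1L] <- paste0("I-", ty)
        }
        cols <- if (with_columns) {
          matrix(sample(c("NN", "JJ", "VB"), n, replace = TRUE), ncol = 1)
        }
        ner_sentence(toks, labels, cols)
      })
      ner_document(sprintf("doc%03d", d), sents)
    })
    ner_corpus(docs)
  })
}

# random mention set over a sentence of length n (non-overlapping)
random_mentions <- function(n, types = c("A", "B")) {
  m <- list()
  pos <- 1L
  while (pos <= n) {
    if (runif(1) < 0.4) {
      len <- sample(1:min(3L, n - pos + 1L), 1L)
      m[[length(m) + 1L]] <- data.frame(
        doc_id = "", sentence_index = 0L, start_token = pos - 1L,
        end_token = pos - 1L + len,
        entity_type = sample(types, 1L), stringsAsFactors = FALSE)
      pos <- pos + len
    } else {
      pos <- pos + 1L
    }
  }
  if (length(m)) do.call(rbind, m) else
    crfvoter:::empty_mentions()
}

# ---- independent CRF oracle ------------------------------------------------

# all |labels|^n labelings as a list of character vectors
enumerate_labelings <- function(labels, n) {
  grid <- expand.grid(rep(list(labels), n), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

# score a labeling by direct weight lookup (no shared code with the
# package's C++ path)
bf_score <- function(model, feature_rows, y) {
  L <- length(model$labels)
  s <- 0
  for (j in seq_along(y)) {
    yi <- match(y[j], model$labels)
    for (f in feature_rows[[j]]) {
      fi <- match(f, model$features)
      if (!is.na(fi)) s <- s + model$W[fi, yi]
    }
    from <- if (j == 1L) L + 1L else match(y[j - 1L], model$labels)
    s <- s + model$Tr[from, yi]
  }
  s
}

# brute-force check of a decoded path against exhaustive enumeration:
# the path must attain the enumerated maximum score; when the argmax is
# unique it must be that labeling exactly. (Exact score ties between
# labelings do occur — e.g. identical feature rows at two positions make
# label swaps score-equivalent — and the decoder resolves them through
# floating-point sums whose order differs from the oracle's, so the tie
# member chosen is not asserted; the deterministic tie rule is covered by
# constructed zero-weight cases.)
expect_viterbi_optimal <- function(model, feature_rows, ys, scores,
                                   eps = 1e-9) {
  dec <- viterbi_decode(model, feature_rows)
  s_dec <- bf_score(model, feature_rows, dec)
  testthat::expect_lt(max(scores) - s_dec, eps)
  top <- which(scores >= max(scores) - eps)
  if (length(top) == 1L) testthat::expect_identical(dec, ys[[top]])
  invisible(dec)
}

random_tiny_model <- function(n_labels = 3L, n_feats = 4L, scale = 1) {
  labels <- c("O", paste0("B-T", seq_len(n_labels - 1L)))
  feats <- paste0("f", seq_len(n_feats))
  crf_model(labels, feats,
            matrix(rnorm(n_feats * n_labels, sd = scale), n_feats),
            matrix(rnorm((n_labels + 1L) * n_labels, sd = scale),
                   n_labels + 1L))
}

random_feature_rows <- function(model, n) {
  lapply(seq_len(n), function(j)
    sample(model$features, sample(seq_along(model$features), 1L)))
}

# ---- independent entity scorer ---------------------------------------------

# per-mention brute-force matcher: for every gold mention scan the whole
# predicted set for an identical row
bf_entity_counts <- function(gold, predicted) {
  same <- function(a, b) {
    a$doc_id == b$doc_id && a$sentence_index == b$sentence_index &&
      a$start_token == b$start_token && a$end_token == b$end_token &&
      a$entity_type == b$entity_type
  }
  tp <- 0L
  for (i in seq_len(nrow(gold))) {
    for (j in seq_len(nrow(predicted))) {
      if (same(gold[i, ], predicted[j, ])) { tp <- tp + 1L; break }
    }
  }
  list(tp = tp, fp = nrow(predicted) - tp, fn = nrow(gold) - tp)
}

# tiny trainable instance set: word identity decides the label
separable_instances <- function(n_sentences = 50L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_sentences), function(i) {
    n <- sample(3:6, 1L)
    words <- sample(c("gene1", "gene2", "the", "binds", "cell"), n,
                    replace = TRUE)
    labels <- ifelse(words %in% c("gene1", "gene2"), "B-GENE", "O")
    list(features = lapply(words, function(w) c("b", paste0("w0=", w))),
         labels = labels)
  })
}
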