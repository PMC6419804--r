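# Seeded generator of synthetic annotated corpora emulating the
# structure of a gene/protein-mention patent corpus: documents of short
# sentences over a pseudo-word background vocabulary, with multi-token
# entity mentions drawn from a typed inventory, and (optionally) a small
# fraction of sub-token "fused" mentions whose gold character span cuts
# inside a token. Also simulates base-labeler outputs with controllable,
# complementary error structure for ensemble benchmarking.

#' Entity class inventory with observed instance counts
#'
#' The eight mention classes of the gene/protein annotation scheme,
#' together with the published per-class instance counts for
#' normalizable (type 1) and non-normalizable (type 2) mentions, used to
#' default the generator's class mixture.
#'
#' @return data.frame with columns `entity_type`, `type_system`
#'   (1 or 2) and `count`.
#' @export
gpro_class_counts <- function() {
  data.frame(
    entity_type = c("ABBREVIATION", "FAMILY", "FULLNAME", "IDENTIFIER",
                    "NESTED",
                    "ABBREVIATION", "FAMILY", "FULLNAME", "MULTIPLE",
                    "NOCLASS", "SEQUENCE"),
    type_system = c(rep(1L, 5L), rep(2L, 6L)),
    count = c(7516L, 1L, 4815L, 1L, 89L,
              27L, 5029L, 27L, 178L, 45L, 23L),
    stringsAsFactors = FALSE
  )
}

default_type_weights <- function() {
  tab <- gpro_class_counts()
  tab <- tab[tab$type_system == 1L, ]
  setNames(tab$count / sum(tab$count), tab$entity_type)
}

#' Generator configuration
#'
#' Defaults state the emulated world: class weights proportional to the
#' published type-1 class counts, 0.85% sub-token special cases, short
#' abstract-like documents.
#'
#' @param n_documents number of documents.
#' @param sentences_per_doc integer range `c(min, max)`.
#' @param tokens_per_sentence integer range `c(min, max)`.
#' @param entity_type_weights named probabilities over entity types
#'   (sum 1 within 1e-9).
#' @param mention_rate expected mentions per sentence (Poisson).
#' @param mention_length_distribution probabilities over mention token
#'   lengths 1..k for classes without an inherent surface pattern.
#' @param entity_vocab,background_vocab lexicon sizes.
#' @param subtoken_case_rate fraction of mentions fused into a
#'   neighboring suffix so their gold span cuts inside a token.
#' @param pos_column also emit a coarse random POS feature column.
#' @param seed integer seed.
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_documents = 100L,
                             sentences_per_doc = c(2L, 4L),
                             tokens_per_sentence = c(8L, 14L),
                             entity_type_weights = default_type_weights(),
                             mention_rate = 1.2,
                             mention_length_distribution =
                               c(`1` = 0.55, `2` = 0.3, `3` = 0.15),
                             entity_vocab = 300L,
                             background_vocab = 2000L,
                             subtoken_case_rate = 0.0085,
                             pos_column = FALSE,
                             seed = 1L) {
  w <- entity_type_weights
  if (is.null(names(w)) || abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
    stop_crf("entity_type_weights must be named, non-negative, sum to 1",
             class = "crfvoter_config")
  }
  if (mention_rate < 0 || subtoken_case_rate < 0 || subtoken_case_rate > 1) {
    stop_crf("rates out of range", class = "crfvoter_config")
  }
  ml <- mention_length_distribution
  if (abs(sum(ml) - 1) > 1e-9) {
    stop_crf("mention_length_distribution must sum to 1",
             class = "crfvoter_config")
  }
  if (max(as.integer(names(ml))) + 1L > tokens_per_sentence[1]) {
    stop_crf("mentions may not fit: max mention length %s vs min sentence %d",
             max(as.integer(names(ml))), tokens_per_sentence[1],
             class = "crfvoter_config")
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 tokens_per_sentence = as.integer(tokens_per_sentence),
                 entity_type_weights = w, mention_rate = mention_rate,
                 mention_length_distribution = ml,
                 entity_vocab = as.integer(entity_vocab),
                 background_vocab = as.integer(background_vocab),
                 subtoken_case_rate = subtoken_case_rate,
                 pos_column = isTRUE(pos_column),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# uniform integer in [a, b], robust to a == b (sample() would misread it)
r_int <- function(a, b) if (a >= b) a else a + sample.int(b - a + 1L, 1L) - 1L

random_word <- function(n, min_len = 3L, max_len = 9L) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(min_len:max_len, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

# surface-form pattern per entity class (documented invention: the class
# inventory is published, example surfaces are not)
make_entity_surface <- function(type, len_dist) {
  caps <- function(w) paste0(toupper(substring(w, 1, 1)), substring(w, 2))
  acronym <- function() {
    a <- paste(sample(LETTERS, sample(2:4, 1L), replace = TRUE),
               collapse = "")
    if (runif(1) < 0.5) a <- paste0(a, sample(0:9, 1L))
    a
  }
  switch(type,
    ABBREVIATION = acronym(),
    FULLNAME = vapply(seq_len(sample(2:4, 1L)),
                      function(i) caps(random_word(1L, 4L, 9L)),
                      character(1)),
    FAMILY = c(caps(random_word(1L, 4L, 8L)),
               sample(c("kinases", "receptors", "family"), 1L)),
    IDENTIFIER = paste0("GPR", paste(sample(0:9, 5L, replace = TRUE),
                                     collapse = "")),
    NESTED = c(acronym(), "domain"),
    MULTIPLE = paste0(acronym(), "/", acronym()),
    SEQUENCE = paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
                     collapse = ""),
    # NOCLASS and anything else: generic mention with sampled length
    {
      k <- as.integer(sample(names(len_dist), 1L, prob = len_dist))
      vapply(seq_len(k), function(i) caps(random_word(1L, 4L, 8L)),
             character(1))
    })
}

.pos_tags <- c("NN", "NNS", "JJ", "VBZ", "IN", "DT", "CD")

#' Generate a synthetic annotated corpus
#'
#' Deterministic given `config$seed`. Entity surfaces follow per-class
#' patterns (uppercase acronyms for ABBREVIATION, multiword capitalized
#' phrases for FULLNAME, suffix-patterned FAMILY names, ...). A
#' `subtoken_case_rate` fraction of mentions is fused with a generated
#' suffix into a single token: the fused mention is dropped from the IOB2
#' labels (it cannot be expressed there) but kept in the character-offset
#' sidecar, exercising [filter_subtoken_mentions()].
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (gold-labeled `ner_corpus`) and `mentions`
#'   (data.frame `doc_id`, `start_char`, `end_char`, `entity_type` over
#'   the document text, including fused sub-token mentions).
#' @export
generate_corpus <- function(config) {
  with_seed(config$seed, {
    types <- names(config$entity_type_weights)
    bg <- unique(random_word(config$background_vocab))
    lex <- lapply(setNames(types, types), function(ty) {
      lapply(seq_len(config$entity_vocab), function(i)
        make_entity_surface(ty, config$mention_length_distribution))
    })
    docs <- vector("list", config$n_documents)
    char_rows <- list()
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("d%04d", d)
      ns <- r_int(config$sentences_per_doc[1], config$sentences_per_doc[2])
      sents <- vector("list", ns)
      doc_char_base <- 0L
      for (si in seq_len(ns)) {
        nt <- r_int(config$tokens_per_sentence[1],
                    config$tokens_per_sentence[2])
        toks <- sample(bg, nt, replace = TRUE)
        labels <- rep("O", nt)
        n_m <- rpois(1L, config$mention_rate)
        occupied <- rep(FALSE, nt)
        fused <- list()
        if (n_m > 0L) for (mi in seq_len(n_m)) {
          ty <- sample(types, 1L, prob = config$entity_type_weights)
          surf <- lex[[ty]][[sample.int(config$entity_vocab, 1L)]]
          L <- length(surf)
          free <- which(!occupied)
          starts <- free[vapply(free, function(s)
            s + L - 1L <= nt && all(!occupied[s:(s + L - 1L)]),
            logical(1))]
          if (length(starts) == 0L) next
          s <- starts[sample.int(length(starts), 1L)]
          toks[s:(s + L - 1L)] <- surf
          occupied[s:(s + L - 1L)] <- TRUE
          if (runif(1) < config$subtoken_case_rate) {
            # fuse: append a suffix to the last mention token; gold char
            # span covers only the original surface (sub-token case)
            suffix <- paste0("V", sample(100:999, 1L),
                             sample(LETTERS, 1L))
            fused[[length(fused) + 1L]] <-
              list(start = s, len = L,
                   surf_chars = sum(nchar(surf)) + (L - 1L), type = ty)
            toks[s + L - 1L] <- paste0(toks[s + L - 1L], suffix)
          } else {
            labels[s] <- paste0("B-", ty)
            if (L > 1L) labels[(s + 1L):(s + L - 1L)] <- paste0("I-", ty)
            fused[[length(fused) + 1L]] <-
              list(start = s, len = L,
                   surf_chars = sum(nchar(surf)) + (L - 1L), type = ty)
          }
        }
        cols <- if (config$pos_column) {
          matrix(sample(.pos_tags, nt, replace = TRUE), ncol = 1L)
        }
        sents[[si]] <- ner_sentence(toks, labels, cols)
        # character offsets of this sentence's mentions over the doc text
        tok_starts <- doc_char_base +
          cumsum(c(0L, head(nchar(toks) + 1L, -1L)))
        for (fm in fused) {
          st <- tok_starts[fm$start]
          char_rows[[length(char_rows) + 1L]] <- data.frame(
            doc_id = doc_id, start_char = st,
            end_char = st + fm$surf_chars, entity_type = fm$type,
            stringsAsFactors = FALSE)
        }
        doc_char_base <- doc_char_base + sum(nchar(toks)) + length(toks)
      }
      docs[[d]] <- ner_document(doc_id, sents)
    }
    mentions <- if (length(char_rows)) do.call(rbind, char_rows) else
      data.frame(doc_id = character(), start_char = integer(),
                 end_char = integer(), entity_type = character(),
                 stringsAsFactors = FALSE)
    list(corpus = ner_corpus(docs), mentions = mentions)
  })
}

#' Error profile of a simulated labeler
#'
#' @param learner_id identifier.
#' @param per_type_miss_rate named per-type probability of deleting a
#'   mention entirely.
#' @param boundary_jitter_rate probability of shifting one mention
#'   boundary by one token.
#' @param type_confusion named per-type probability of relabeling a
#'   mention with a random other type.
#' @param seed integer seed (one per profile).
#' @return an `error_profile` object.
#' @export
error_profile <- function(learner_id, per_type_miss_rate = c(),
                          boundary_jitter_rate = 0,
                          type_confusion = c(), seed = 1L) {
  probs <- c(unlist(per_type_miss_rate), boundary_jitter_rate,
             unlist(type_confusion))
  if (length(probs) && (any(probs < 0) || any(probs > 1))) {
    stop_crf("profile probabilities must lie in [0, 1]",
             class = "crfvoter_config")
  }
  structure(list(learner_id = learner_id,
                 per_type_miss_rate = per_type_miss_rate,
                 boundary_jitter_rate = boundary_jitter_rate,
                 type_confusion = type_confusion,
                 seed = as.integer(seed)),
            class = "error_profile")
}

#' Simulate a labeler's output by corrupting gold mentions
#'
#' Applies per-type deletions, one-token boundary jitter and type
#' confusion to each sentence's gold mentions, then re-encodes IOB2.
#' Errors are deletion/distortion only; the simulated labelers never
#' hallucinate mentions on unannotated tokens, so their precision is
#' high by construction. Deterministic given the profile seed.
#'
#' @param corpus gold `ner_corpus`.
#' @param profile an [error_profile()].
#' @return predicted tagging: list of tag vectors in corpus order.
#' @export
simulate_learner_output <- function(corpus, profile) {
  types <- names(profile$per_type_miss_rate)
  with_seed(profile$seed, {
    out <- list(); k <- 0L
    for (doc in corpus$documents) {
      for (s in doc$sentences) {
        k <- k + 1L
        n <- length(s)
        mentions <- iob_to_spans(s$labels)
        keep <- list()
        if (nrow(mentions)) for (i in seq_len(nrow(mentions))) {
          m <- mentions[i, , drop = FALSE]
          miss <- profile$per_type_miss_rate[[m$entity_type]] %||% 0
          if (runif(1) < miss) next
          if (runif(1) < profile$boundary_jitter_rate) {
            if (runif(1) < 0.5) {
              m$start_token <- max(0L, m$start_token - 1L)
            } else {
              m$end_token <- min(n, m$end_token + 1L)
            }
          }
          conf <- profile$type_confusion[[m$entity_type]] %||% 0
          if (runif(1) < conf) {
            others <- setdiff(types, m$entity_type)
            if (length(others)) {
              m$entity_type <- others[sample.int(length(others), 1L)]
            }
          }
          keep[[length(keep) + 1L]] <- m
        }
        tags <- rep("O", n)
        if (length(keep)) {
          km <- do.call(rbind, keep)
          km <- km[order(km$start_token), , drop = FALSE]
          # drop overlaps introduced by jitter (earlier mention wins)
          sel <- rep(TRUE, nrow(km))
          last_end <- -1L
          for (i in seq_len(nrow(km))) {
            if (km$start_token[i] < last_end) sel[i] <- FALSE
            else last_end <- km$end_token[i]
          }
          tags <- spans_to_iob(n, km[sel, , drop = FALSE])
        }
        out[[k]] <- tags
      }
    }
    out
  })
}

#' Build the complementary-error ensemble benchmark
#'
#' Generates a corpus over `l` equally weighted entity types, splits it
#' 60/20/20 by document, and assigns each of `l` simulated labelers a
#' distinct near-blind entity type (miss rate `blind_miss`) while all
#' other types are missed at `base_miss`. Errors are therefore
#' systematically disjoint across labelers: every mention missed by one
#' labeler is usually recovered by another, but typically by only one of
#' them, which is exactly the regime where positionwise majority voting
#' fails and a trained second-level combiner can win.
#'
#' @param config a [generator_config()]; its type weights are replaced by
#'   uniform weights over the first `l` inventory types.
#' @param l number of simulated labelers (>= 2).
#' @param seed master seed.
#' @param blind_miss miss rate on the labeler's own blind type.
#' @param base_miss miss rate on every other type.
#' @param jitter boundary jitter rate.
#' @return list with `train`, `dev`, `test` corpora, `profiles` (list of
#'   [error_profile()]), and `mentions` (character-offset sidecar).
#' @export
make_complementary_benchmark <- function(config = generator_config(),
                                         l = 3L, seed = 1L,
                                         blind_miss = 0.95,
                                         base_miss = 0.45,
                                         jitter = 0.02) {
  types <- names(config$entity_type_weights)
  if (l < 2L) stop_crf("need l >= 2 labelers", class = "crfvoter_config")
  if (l > length(types)) {
    stop_crf("l = %d exceeds the %d configured entity types", l,
             length(types), class = "crfvoter_config")
  }
  types <- types[seq_len(l)]
  config$entity_type_weights <- setNames(rep(1 / l, l), types)
  config$seed <- derive_seed(seed, 1L)
  gen <- generate_corpus(config)
  parts <- split_corpus(gen$corpus, c(0.6, 0.2, 0.2),
                        seed = derive_seed(seed, 2L))
  profiles <- lapply(seq_len(l), function(m) {
    miss <- setNames(rep(base_miss, l), types)
    miss[types[m]] <- blind_miss
    error_profile(paste0("sim", m), per_type_miss_rate = as.list(miss),
                  boundary_jitter_rate = jitter,
                  seed = derive_seed(seed, 10L + m))
  })
  c(parts, list(profiles = profiles, mentions = gen$mentions))
}
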