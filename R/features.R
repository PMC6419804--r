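# Sparse feature-template engine.
#
# Each switch contributes an independent generator of string-valued
# indicator features; the emitted set is exactly the union of the enabled
# generators, so enabling a switch can only add features (monotonicity).
# The switch inventory mirrors the tunable surface of a classic
# CRF-based named entity recognizer; the generators themselves are this
# package's own, fully specified emulations, not a re-implementation of
# any external tool. Out-of-bounds context positions emit the sentinels
# "<S>" (left) and "</S>" (right).

.fc_switches <- c(
  "use_word", "use_class_feature", "use_ngrams", "no_mid_ngrams",
  "normalize_terms", "use_position", "use_neighbor_ngrams",
  "use_more_neighbor_ngrams", "use_prev", "use_next", "use_tags",
  "use_word_pairs", "use_disjunctive", "use_sequences",
  "use_prev_sequences", "use_next_sequences", "use_long_sequences",
  "use_taggy_sequences", "use_sym_word_pairs", "use_sym_tags",
  "use_type_seqs", "use_type_seqs2", "use_typey_sequences",
  "use_gaz_features", "use_word_tag", "use_wide_disjunctive",
  "use_lemmas", "use_prev_next_lemmas", "sloppy_gazette")

#' Feature template configuration
#'
#' Boolean switches select feature generators; integer knobs bound the
#' context window (`max_left`, `max_right` in 1..6) and character n-gram
#' length (`max_ngram_leng` in 1..6); `word_shape` names the registered
#' shape function used by shape-based generators. `tag_column` and
#' `lemma_column` are 1-based indices into the sentence's extra feature
#' columns; tag/lemma generators are silently skipped when the column is
#' absent. `normalize_terms` lowercases the word-identity feature only.
#'
#' @param ... switch values by name; unknown names are rejected.
#' @param max_left,max_right,max_ngram_leng integer knobs in 1..6.
#' @param word_shape one of `"chris2uselc"` (run-compressed,
#'   lowercase-preserving style) or `"plain"`.
#' @param tag_column,lemma_column optional 1-based column indices.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(..., max_left = 2L, max_right = 2L,
                           max_ngram_leng = 4L, word_shape = "chris2uselc",
                           tag_column = NULL, lemma_column = NULL) {
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots))))) {
    stop_crf("all switch arguments must be named", class = "crfvoter_config")
  }
  unknown <- setdiff(names(dots), .fc_switches)
  if (length(unknown)) {
    stop_crf("unknown feature switch(es): %s",
             paste(unknown, collapse = ", "), class = "crfvoter_config")
  }
  cfg <- as.list(setNames(rep(FALSE, length(.fc_switches)), .fc_switches))
  for (nm in names(dots)) cfg[[nm]] <- isTRUE(dots[[nm]])
  for (knob in c("max_left", "max_right", "max_ngram_leng")) {
    v <- as.integer(get(knob))
    if (is.na(v) || v < 1L || v > 6L) {
      stop_crf("%s must be an integer in 1..6", knob,
               class = "crfvoter_config")
    }
    cfg[[knob]] <- v
  }
  if (!word_shape %in% names(.shape_registry)) {
    stop_crf("unknown word_shape mode '%s'", word_shape,
             class = "crfvoter_config")
  }
  cfg$word_shape <- word_shape
  cfg$tag_column <- if (!is.null(tag_column)) as.integer(tag_column)
  cfg$lemma_column <- if (!is.null(lemma_column)) as.integer(lemma_column)
  structure(cfg, class = "feature_config")
}

# shape registry -------------------------------------------------------------

shape_translit <- function(surface) {
  ch <- strsplit(surface, "", fixed = TRUE)[[1]]
  out <- ch
  out[grepl("[A-Z]", ch)] <- "X"
  out[grepl("[a-z]", ch)] <- "x"
  out[grepl("[0-9]", ch)] <- "0"
  out
}

.shape_registry <- list(
  plain = function(surface) paste(shape_translit(surface), collapse = ""),
  # run-compressed variant: runs of the same shape character longer than 4
  # are collapsed to 4 occurrences
  chris2uselc = function(surface) {
    sh <- shape_translit(surface)
    r <- rle(sh)
    r$lengths <- pmin(r$lengths, 4L)
    paste(inverse.rle(r), collapse = "")
  }
)

#' Character-class word shape
#'
#' Transliterates uppercase letters to `X`, lowercase to `x`, digits to
#' `0`; any other character maps to itself. Mode `"chris2uselc"`
#' additionally collapses runs of more than four identical shape
#' characters to four.
#'
#' @param surface token surface string.
#' @param mode registered shape function name.
#' @return shape string.
#' @export
word_shape <- function(surface, mode = "chris2uselc") {
  fn <- .shape_registry[[mode]]
  if (is.null(fn)) {
    stop_crf("unknown word_shape mode '%s'", mode, class = "crfvoter_config")
  }
  vapply(surface, fn, character(1), USE.NAMES = FALSE)
}

#' Character n-grams of a token
#'
#' All substrings of length at most `max_len`; with `no_mid = TRUE` only
#' prefixes and suffixes are kept. With `mark_boundaries = TRUE` (the
#' default used by the feature generators) prefix n-grams are additionally
#' emitted with a leading `<` and suffix n-grams with a trailing `>`.
#'
#' @param surface token surface string.
#' @param max_len maximum n-gram length (>= 1).
#' @param no_mid keep only prefixes/suffixes.
#' @param mark_boundaries also emit boundary-marked variants.
#' @return character vector of unique n-grams.
#' @export
char_ngrams <- function(surface, max_len = 4L, no_mid = FALSE,
                        mark_boundaries = TRUE) {
  stopifnot(max_len >= 1L)
  L <- nchar(surface)
  if (L == 0L) return(character(0))
  grams <- character(0)
  pref <- character(0); suf <- character(0)
  for (k in seq_len(min(max_len, L))) {
    subs <- substring(surface, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    pref <- c(pref, subs[1L])
    suf <- c(suf, subs[length(subs)])
    grams <- c(grams, subs)
  }
  if (no_mid) grams <- unique(c(pref, suf))
  out <- grams
  if (mark_boundaries) {
    out <- c(out, paste0("<", pref), paste0(suf, ">"))
  }
  unique(out)
}

#' Read a gazetteer
#'
#' Two-column TSV: surface phrase (whitespace-tokenized), entity type.
#'
#' @param path file path.
#' @return a `gazetteer` object.
#' @export
read_gazetteer <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop_crf("gazetteer lines must have exactly 2 tab-separated fields",
             class = "crfvoter_format")
  }
  gazetteer(vapply(parts, `[`, character(1), 1L),
            vapply(parts, `[`, character(1), 2L))
}

#' Construct a gazetteer from phrases and types
#' @param phrases character vector of non-empty surface phrases.
#' @param types parallel character vector of entity types.
#' @return a `gazetteer` object.
#' @export
gazetteer <- function(phrases, types) {
  stopifnot(length(phrases) == length(types), all(nzchar(phrases)))
  toks <- strsplit(phrases, "\\s+")
  structure(list(phrases = phrases, types = types, tokens = toks,
                 token_index = split(rep(types, lengths(toks)),
                                     unlist(toks))),
            class = "gazetteer")
}

# context accessor with boundary sentinels
.ctx <- function(vec, pos, off) {
  i <- pos + off
  n <- length(vec)
  if (i < 1L) "<S>" else if (i > n) "</S>" else vec[i]
}

#' Extract the sparse feature set at one token position
#'
#' @param sentence an [ner_sentence()].
#' @param position 1-based token position.
#' @param config a [feature_config()].
#' @param gaz optional [gazetteer()].
#' @return sorted character vector of unique feature strings. A constant
#'   bias feature `"b"` is always present so the all-off configuration
#'   stays trainable.
#' @export
extract_features <- function(sentence, position, config, gaz = NULL) {
  n <- length(sentence)
  if (position < 1L || position > n) {
    stop_crf("position %d out of range 1..%d", position, n,
             class = "crfvoter_index")
  }
  surf <- sentence$surface
  w <- function(off) .ctx(surf, position, off)
  tags <- NULL; lemmas <- NULL
  if (!is.null(sentence$columns)) {
    nc <- ncol(sentence$columns)
    if (!is.null(config$tag_column) && config$tag_column <= nc) {
      tags <- sentence$columns[, config$tag_column]
    }
    if (!is.null(config$lemma_column) && config$lemma_column <= nc) {
      lemmas <- sentence$columns[, config$lemma_column]
    }
  }
  tg <- function(off) .ctx(tags, position, off)
  lm <- function(off) .ctx(lemmas, position, off)
  sh <- function(off) {
    x <- w(off)
    if (x %in% c("<S>", "</S>")) x else word_shape(x, config$word_shape)
  }
  w0 <- if (config$normalize_terms) tolower(w(0L)) else w(0L)

  f <- "b"
  add <- function(...) f <<- c(f, ...)

  if (config$use_word) add(paste0("w0=", w0))
  if (config$use_class_feature) add(paste0("sh0=", sh(0L)))
  if (config$use_ngrams) {
    add(paste0("ng=", char_ngrams(w(0L), config$max_ngram_leng,
                                  config$no_mid_ngrams)))
  }
  if (config$use_neighbor_ngrams) {
    add(paste0("ngp=", char_ngrams(w(-1L), config$max_ngram_leng,
                                   config$no_mid_ngrams)),
        paste0("ngn=", char_ngrams(w(1L), config$max_ngram_leng,
                                   config$no_mid_ngrams)))
  }
  if (config$use_more_neighbor_ngrams) {
    add(paste0("ngp2=", char_ngrams(w(-2L), config$max_ngram_leng,
                                    config$no_mid_ngrams)),
        paste0("ngn2=", char_ngrams(w(2L), config$max_ngram_leng,
                                    config$no_mid_ngrams)))
  }
  if (config$use_position) {
    if (position == 1L) add("posn=first")
    if (position == n) add("posn=last")
    add(paste0("posq=", floor(4 * (position - 1L) / n)))
  }
  if (config$use_prev) add(paste0("w-1=", w(-1L)))
  if (config$use_next) add(paste0("w+1=", w(1L)))
  if (config$use_tags && !is.null(tags)) {
    add(paste0("t0=", tg(0L)), paste0("t-1=", tg(-1L)),
        paste0("t+1=", tg(1L)))
  }
  if (config$use_word_pairs) {
    add(paste0("wp=", w(-1L), "|", w(0L)),
        paste0("wn=", w(0L), "|", w(1L)))
  }
  if (config$use_sym_word_pairs) add(paste0("swp=", w(-1L), "|", w(1L)))
  if (config$use_disjunctive) {
    for (d in 1:4) add(paste0("dl=", w(-d)), paste0("dr=", w(d)))
  }
  if (config$use_wide_disjunctive) {
    for (d in 1:8) add(paste0("wdl=", w(-d)), paste0("wdr=", w(d)))
  }
  if (config$use_sequences) {
    add(paste0("s3=", w(-1L), "_", w(0L), "_", w(1L)))
  }
  if (config$use_prev_sequences) add(paste0("pseq=", w(-2L), "_", w(-1L)))
  if (config$use_next_sequences) add(paste0("nseq=", w(1L), "_", w(2L)))
  if (config$use_long_sequences) {
    add(paste0("ls=", paste(vapply(-config$max_left:0, w, character(1)),
                            collapse = "_")),
        paste0("rs=", paste(vapply(0:config$max_right, w, character(1)),
                            collapse = "_")))
  }
  if (config$use_taggy_sequences && !is.null(tags)) {
    add(paste0("tseq=", tg(-2L), "_", tg(-1L), "_", tg(0L)))
  }
  if (config$use_sym_tags && !is.null(tags)) {
    add(paste0("stp=", tg(-1L), "|", tg(1L)))
  }
  if (config$use_type_seqs) add(paste0("sh_s=", sh(-1L), "_", sh(0L)))
  if (config$use_type_seqs2) add(paste0("sh_s2=", sh(0L), "_", sh(1L)))
  if (config$use_typey_sequences) {
    add(paste0("sh_ty=", sh(-1L), "_", sh(0L), "_", sh(1L)))
  }
  if (config$use_word_tag && !is.null(tags)) {
    add(paste0("wt0=", w0, "|", tg(0L)))
  }
  if (config$use_lemmas && !is.null(lemmas)) add(paste0("l0=", lm(0L)))
  if (config$use_prev_next_lemmas && !is.null(lemmas)) {
    add(paste0("l-1=", lm(-1L)), paste0("l+1=", lm(1L)))
  }
  if (!is.null(gaz)) {
    if (config$use_gaz_features) {
      # exact phrase hit: any gazetteer phrase whose token sequence covers
      # this position (phrase lengths up to 5 considered)
      for (gi in seq_along(gaz$tokens)) {
        ph <- gaz$tokens[[gi]]
        L <- length(ph)
        if (L > 5L) next
        for (s in max(1L, position - L + 1L):min(position, n - L + 1L)) {
          if (s < 1L || s + L - 1L > n) next
          if (identical(surf[s:(s + L - 1L)], ph)) {
            add(paste0("gaz=", gaz$types[gi]))
            break
          }
        }
      }
    }
    if (config$sloppy_gazette) {
      hit <- gaz$token_index[[w(0L)]]
      if (!is.null(hit)) add(paste0("gazs=", unique(hit)))
    }
  }
  sort(unique(f))
}

#' Feature rows for a whole sentence
#' @param sentence an [ner_sentence()].
#' @param config a [feature_config()].
#' @param gaz optional gazetteer.
#' @return list of character vectors, one per token.
#' @export
sentence_features <- function(sentence, config, gaz = NULL) {
  lapply(seq_len(length(sentence)), extract_features,
         sentence = sentence, config = config, gaz = gaz)
}
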