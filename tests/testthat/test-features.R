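# features: switch semantics, shapes, n-grams, determinism, locality and
# switch monotonicity.

sent2 <- function() ner_sentence(c("EGFR", "binds"))

test_that("single-switch and all-off configurations", {
  f <- extract_features(sent2(), 1L, feature_config(use_word = TRUE))
  expect_setequal(f, c("b", "w0=EGFR"))
  expect_setequal(extract_features(sent2(), 1L, feature_config()), "b")
  expect_error(extract_features(sent2(), 3L, feature_config()),
               class = "crfvoter_index")
  expect_error(feature_config(use_wibble = TRUE),
               class = "crfvoter_config")
  expect_error(feature_config(max_left = 9), class = "crfvoter_config")
})

test_that("context features use boundary sentinels and normalization", {
  cfg <- feature_config(use_prev = TRUE, use_next = TRUE,
                        use_word = TRUE, normalize_terms = TRUE)
  f <- extract_features(sent2(), 1L, cfg)
  expect_true(all(c("w-1=<S>", "w+1=binds", "w0=egfr") %in% f))
  f2 <- extract_features(sent2(), 2L, cfg)
  expect_true("w+1=</S>" %in% f2)
})

test_that("word_shape matches the transliteration oracle", {
  expect_equal(word_shape("EGFR", "plain"), "XXXX")
  expect_equal(word_shape("p53", "plain"), "x00")
  expect_error(word_shape("x", "nope"), class = "crfvoter_config")

  oracle <- function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(vapply(ch, function(c) {
      if (grepl("[A-Z]", c)) "X" else if (grepl("[a-z]", c)) "x"
      else if (grepl("[0-9]", c)) "0" else c
    }, character(1)), collapse = "")
  }
  set.seed(5)
  pool <- c(LETTERS, letters, 0:9, "-", ".")
  for (i in 1:50) {
    s <- paste(sample(pool, sample(1:12, 1L), replace = TRUE),
               collapse = "")
    expect_identical(word_shape(s, "plain"), oracle(s))
  }
  # run compression in the lowercase-style mode
  expect_equal(word_shape("ABCDEFG", "chris2uselc"), "XXXX")
  expect_equal(word_shape("B-RafV600E", "chris2uselc"),
               word_shape("B-RafV600E", "plain"))  # no run exceeds 4
})

test_that("char_ngrams enumerates substrings with boundary marks", {
  expect_setequal(char_ngrams("abc", 2L, FALSE),
                  c("a", "b", "c", "ab", "bc", "<a", "<ab", "c>", "bc>"))
  expect_setequal(char_ngrams("abc", 2L, TRUE),
                  c("a", "c", "ab", "bc", "<a", "<ab", "c>", "bc>"))
  # closed form: sum_{k=1..min(n,L)} (L-k+1), on distinct-character strings
  for (L in 1:8) for (n in 1:5) {
    s <- paste(letters[1:L], collapse = "")
    expect_length(char_ngrams(s, n, FALSE, mark_boundaries = FALSE),
                  sum(L - seq_len(min(n, L)) + 1L))
  }
})

# no_mid_ngrams and normalize_terms are modifier switches (they change
# what other generators emit rather than adding a generator), so the
# monotonicity property quantifies over the generator switches only
additive_switches <- setdiff(crfvoter:::.fc_switches,
                             c("no_mid_ngrams", "normalize_terms"))

random_config <- function() {
  switches <- sample(crfvoter:::.fc_switches, sample(0:6, 1L))
  args <- setNames(as.list(rep(TRUE, length(switches))), switches)
  do.call(feature_config, c(args, list(tag_column = 1L, lemma_column = 1L)))
}

test_that("enabling a switch never removes features (monotonicity)", {
  set.seed(11)
  s <- ner_sentence(rand_word(6),
                    columns = matrix(sample(c("NN", "JJ"), 6, TRUE)))
  for (i in 1:40) {
    cfg <- random_config()
    off <- names(which(!unlist(cfg[additive_switches])))
    if (!length(off)) next
    extra <- sample(off, 1L)
    cfg2 <- cfg
    cfg2[[extra]] <- TRUE
    pos <- sample(1:6, 1L)
    f1 <- extract_features(s, pos, cfg)
    f2 <- extract_features(s, pos, cfg2)
    expect_true(all(f1 %in% f2),
                info = sprintf("switch %s removed features", extra))
  }
})

test_that("features are deterministic and local to the context window", {
  set.seed(21)
  toks <- rand_word(11)
  s <- ner_sentence(toks)
  cfg <- feature_config(use_word = TRUE, use_prev = TRUE, use_next = TRUE,
                        use_sequences = TRUE, use_prev_sequences = TRUE,
                        use_next_sequences = TRUE, use_type_seqs = TRUE,
                        max_left = 2L, max_right = 2L,
                        use_long_sequences = TRUE)
  pos <- 6L
  f1 <- extract_features(s, pos, cfg)
  expect_identical(f1, extract_features(s, pos, cfg))
  # mutate tokens outside [pos-2, pos+2]: features must not change
  toks2 <- toks
  toks2[c(1:3, 9:11)] <- rand_word(6)
  expect_identical(extract_features(ner_sentence(toks2), pos, cfg), f1)
})

test_that("gazetteer features fire on exact and sloppy hits", {
  gaz <- gazetteer(c("epidermal growth factor", "EGFR"),
                   c("FULLNAME", "ABBREVIATION"))
  s <- ner_sentence(c("the", "epidermal", "growth", "factor", "binds"))
  cfg <- feature_config(use_gaz_features = TRUE, sloppy_gazette = TRUE)
  f <- extract_features(s, 3L, cfg, gaz)
  expect_true("gaz=FULLNAME" %in% f)
  expect_true("gazs=FULLNAME" %in% f)
  expect_false(any(grepl("^gaz", extract_features(s, 1L, cfg, gaz))))
})

test_that("tag and lemma generators read columns and skip when absent", {
  cols <- cbind(c("NN", "VBZ"), c("egfr", "bind"))
  s <- ner_sentence(c("EGFR", "binds"), columns = cols)
  cfg <- feature_config(use_tags = TRUE, use_lemmas = TRUE,
                        use_word_tag = TRUE, use_word = TRUE,
                        tag_column = 1L, lemma_column = 2L)
  f <- extract_features(s, 1L, cfg)
  expect_true(all(c("t0=NN", "l0=egfr", "wt0=EGFR|NN") %in% f))
  # same config, no columns: tag/lemma features silently absent
  f2 <- extract_features(sent2(), 1L, cfg)
  expect_false(any(grepl("^(t0|l0|wt0)=", f2)))
})
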