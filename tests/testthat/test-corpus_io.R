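# corpus_io: TSV round-trips, IOB2 span conversion, sub-token filtering,
# document-level splitting.

test_that("read_corpus_tsv parses tokens, labels and degenerate input", {
  path <- withr_tempfile <- tempfile(fileext = ".tsv")
  writeLines(c("EGFR\tB-FULLNAME", "binds\tO"), path)
  corp <- read_corpus_tsv(path)
  expect_length(corp$documents, 1L)
  s <- corp$documents[[1]]$sentences
  expect_length(s, 1L)
  expect_equal(s[[1]]$surface, c("EGFR", "binds"))
  expect_equal(s[[1]]$labels, c("B-FULLNAME", "O"))

  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_length(read_corpus_tsv(empty)$documents, 0L)

  expect_error(read_corpus_tsv(tempfile()), class = "crfvoter_io")
})

test_that("ragged columns raise a format error naming the line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("a\tNN\tO", "b\tO"), path)
  err <- expect_error(read_corpus_tsv(path), class = "crfvoter_format")
  expect_match(conditionMessage(err), "line 2")
})

test_that("invalid IOB2 labels are repaired on read with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("a\tI-X", "b\tI-X"), path)
  expect_warning(corp <- read_corpus_tsv(path), "repaired")
  expect_equal(corp$documents[[1]]$sentences[[1]]$labels, c("B-X", "I-X"))
})

test_that("write/read round-trips random corpora exactly", {
  for (seed in 1:100) {
    corp <- random_test_corpus(seed, n_docs = sample(1:3, 1L),
                               with_columns = seed %% 2L == 0L)
    path <- tempfile(fileext = ".tsv")
    write_corpus_tsv(corp, path)
    back <- read_corpus_tsv(path)
    expect_equal(back, corp, ignore_attr = FALSE)
    # byte-level stability of re-serialization
    path2 <- tempfile(fileext = ".tsv")
    write_corpus_tsv(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("spans_to_iob encodes, rejects overlaps, keeps IOB2 adjacency", {
  m1 <- data.frame(start_token = 2L, end_token = 4L,
                   entity_type = "FULLNAME")
  expect_equal(spans_to_iob(5L, m1),
               c("O", "O", "B-FULLNAME", "I-FULLNAME", "O"))
  expect_equal(spans_to_iob(3L, NULL), c("O", "O", "O"))

  adj <- data.frame(start_token = c(0L, 2L), end_token = c(2L, 4L),
                    entity_type = c("FAMILY", "FAMILY"))
  expect_equal(spans_to_iob(4L, adj),
               c("B-FAMILY", "I-FAMILY", "B-FAMILY", "I-FAMILY"))

  ov <- data.frame(start_token = c(0L, 1L), end_token = c(2L, 3L),
                   entity_type = c("A", "B"))
  expect_error(spans_to_iob(4L, ov), class = "crfvoter_overlap")
  out <- data.frame(start_token = 3L, end_token = 5L, entity_type = "A")
  expect_error(spans_to_iob(4L, out), class = "crfvoter_span_bounds")
})

test_that("iob_to_spans inverts spans_to_iob on 200 random mention sets", {
  expect_equal(iob_to_spans(c("B-X", "I-X", "O"))$start_token, 0L)
  expect_equal(nrow(iob_to_spans(c("O", "O"))), 0L)
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:12, 1L)
    m <- random_mentions(n)
    tags <- spans_to_iob(n, m)
    back <- iob_to_spans(tags)
    m_sorted <- m[order(m$start_token), c("start_token", "end_token",
                                          "entity_type")]
    rownames(m_sorted) <- NULL
    expect_equal(back[, c("start_token", "end_token", "entity_type")],
                 m_sorted)
  }
})

test_that("filter_subtoken_mentions routes fused spans and conserves", {
  # doc text: "the B-RafV600E binds EGFR" with a sub-token gold span over
  # "B-Raf" (chars 4..9) and an aligned span over "EGFR" (chars 21..25)
  corp <- ner_corpus(list(ner_document("d1", list(
    ner_sentence(c("the", "B-RafV600E", "binds", "EGFR"))))))
  gold <- data.frame(
    doc_id = "d1", start_char = c(4L, 21L), end_char = c(9L, 25L),
    entity_type = c("FULLNAME", "ABBREVIATION"), stringsAsFactors = FALSE)
  parts <- filter_subtoken_mentions(corp, gold)
  expect_equal(nrow(parts$trainable), 1L)
  expect_equal(parts$trainable$start_token, 3L)
  expect_equal(parts$trainable$entity_type, "ABBREVIATION")
  expect_equal(nrow(parts$untrainable), 1L)
  expect_equal(parts$untrainable$entity_type, "FULLNAME")
  expect_equal(nrow(parts$trainable) + nrow(parts$untrainable), nrow(gold))

  bad <- data.frame(doc_id = "d1", start_char = 0L, end_char = 999L,
                    entity_type = "X", stringsAsFactors = FALSE)
  expect_error(filter_subtoken_mentions(corp, bad),
               class = "crfvoter_range")
})

test_that("split_corpus partitions deterministically with remainder to train", {
  corp <- random_test_corpus(7, n_docs = 100L)
  parts <- split_corpus(corp, c(0.6, 0.2, 0.2), seed = 7)
  expect_equal(vapply(parts, function(p) length(p$documents), integer(1)),
               c(train = 60L, dev = 20L, test = 20L))
  parts2 <- split_corpus(corp, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(parts, parts2)

  ids <- function(p) vapply(p$documents, `[[`, character(1), "doc_id")
  all_ids <- sort(unname(unlist(lapply(parts, ids))))
  expect_equal(all_ids, sort(ids(corp)))
  expect_length(intersect(ids(parts$train), ids(parts$dev)), 0L)
  expect_length(intersect(ids(parts$train), ids(parts$test)), 0L)
  expect_length(intersect(ids(parts$dev), ids(parts$test)), 0L)

  # 101 documents: the leftover goes to train
  corp101 <- random_test_corpus(8, n_docs = 101L)
  p101 <- split_corpus(corp101, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(length(p101$train$documents), 61L)

  expect_error(split_corpus(random_test_corpus(1, n_docs = 2L)),
               class = "crfvoter_degenerate_split")
  expect_error(split_corpus(corp, c(0.5, 0.2, 0.2)),
               class = "crfvoter_ratios")
})

test_that("tokenize_nonalnum keeps separators, drops whitespace", {
  expect_equal(tokenize_nonalnum("B-RafV600E"), c("B", "-", "RafV600E"))
  expect_equal(tokenize_nonalnum("IL-2 receptor"),
               c("IL", "-", "2", "receptor"))
})
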