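# Corpus containers and CoNLL-style TSV I/O.
#
# A corpus is a list of documents; a document carries a doc_id and a list
# of sentences; a sentence stores parallel vectors: token surfaces, an
# optional character matrix of extra feature columns (lemma, POS, ...) and
# one IOB2 label per token. Mentions travel as plain data.frames with
# columns doc_id, sentence_index, start_token, end_token, entity_type
# (token indices 0-based, half-open).

#' Construct a labeled sentence
#'
#' @param surface character vector of token surfaces (non-empty, no tabs
#'   or newlines).
#' @param labels IOB2 tags, one per token; defaults to all-"O".
#' @param columns optional character matrix of per-token feature columns
#'   (e.g. lemma, POS), `nrow(columns) == length(surface)`.
#' @param repair if `TRUE` (default) invalid I- continuations are rewritten
#'   to B- with a warning; if `FALSE` invalid labels are an error.
#' @return an object of class `ner_sentence`.
#' @export
ner_sentence <- function(surface, labels = NULL, columns = NULL,
                         repair = TRUE) {
  surface <- as.character(surface)
  if (length(surface) == 0L) {
    stop_crf("a sentence must contain at least one token",
             class = "crfvoter_empty_sentence")
  }
  if (any(!nzchar(surface)) || any(grepl("[\t\n]", surface))) {
    stop_crf("token surfaces must be non-empty and free of tab/newline",
             class = "crfvoter_bad_token")
  }
  if (is.null(labels)) labels <- rep("O", length(surface))
  labels <- as.character(labels)
  if (length(labels) != length(surface)) {
    stop_crf("labels and surface differ in length (%d vs %d)",
             length(labels), length(surface), class = "crfvoter_length")
  }
  labels <- repair_iob(labels, strict = !repair)
  if (!is.null(columns)) {
    columns <- as.matrix(columns)
    storage.mode(columns) <- "character"
    if (nrow(columns) != length(surface)) {
      stop_crf("columns must have one row per token",
               class = "crfvoter_length")
    }
  }
  structure(list(surface = surface, labels = labels, columns = columns),
            class = "ner_sentence")
}

#' @export
length.ner_sentence <- function(x) length(x$surface)

#' Construct a document
#' @param doc_id document identifier (unique within a corpus).
#' @param sentences list of [ner_sentence()] objects.
#' @return an object of class `ner_document`.
#' @export
ner_document <- function(doc_id, sentences) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!all(vapply(sentences, inherits, logical(1), "ner_sentence"))) {
    stop_crf("all sentences must be ner_sentence objects",
             class = "crfvoter_type")
  }
  structure(list(doc_id = doc_id, sentences = sentences),
            class = "ner_document")
}

#' Construct a corpus
#' @param documents list of [ner_document()] objects with unique ids.
#' @return an object of class `ner_corpus`.
#' @export
ner_corpus <- function(documents = list()) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop_crf("duplicate doc_id in corpus: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             class = "crfvoter_dup_doc")
  }
  structure(list(documents = documents), class = "ner_corpus")
}

#' @export
length.ner_corpus <- function(x) length(x$documents)

#' @export
print.ner_corpus <- function(x, ...) {
  ns <- sum(vapply(x$documents, function(d) length(d$sentences), integer(1)))
  nt <- sum(unlist(lapply(x$documents, function(d)
    vapply(d$sentences, length, integer(1)))), 0L)
  cat(sprintf("<ner_corpus: %d documents, %d sentences, %d tokens>\n",
              length(x$documents), ns, nt))
  invisible(x)
}

n_sentences <- function(corpus) {
  sum(vapply(corpus$documents, function(d) length(d$sentences), integer(1)))
}

# Flat list of sentences in corpus order (documents then sentences).
corpus_sentences <- function(corpus) {
  unlist(lapply(corpus$documents, function(d) d$sentences),
         recursive = FALSE) %||% list()
}

#' Gold labels of a corpus
#'
#' @param corpus an `ner_corpus`.
#' @return list with one character vector of IOB2 tags per sentence, in
#'   corpus order. Predictions produced by the package's taggers use the
#'   same shape, so gold and predicted taggings are directly comparable.
#' @export
corpus_labels <- function(corpus) {
  lapply(corpus_sentences(corpus), function(s) s$labels)
}

is_valid_iob2 <- function(labels) {
  ok <- labels == "O" | grepl("^[BI]-.+$", labels)
  if (!all(ok)) return(FALSE)
  prev <- "O"
  for (lab in labels) {
    if (startsWith(lab, "I-")) {
      ty <- substring(lab, 3)
      if (prev == "O" || substring(prev, 3) != ty) return(FALSE)
    }
    prev <- lab
  }
  TRUE
}

#' Repair a label sequence to valid IOB2
#'
#' An `I-TYPE` tag that follows "O", the sentence start, or a tag of a
#' different type is rewritten to `B-TYPE` (standard IOB repair), with a
#' warning. Tags that are neither "O" nor `B-`/`I-` plus a type are an
#' error: decoding must be total, but arbitrary strings are not labels.
#'
#' @param labels character vector of tags.
#' @param strict if `TRUE`, invalid continuations are an error instead.
#' @return repaired character vector.
#' @export
repair_iob <- function(labels, strict = FALSE) {
  bad <- !(labels == "O" | grepl("^[BI]-.+$", labels))
  if (any(bad)) {
    stop_crf("not an IOB2 tag: '%s'", labels[which(bad)[1]],
             class = "crfvoter_bad_label")
  }
  out <- labels
  prev <- "O"
  changed <- FALSE
  for (i in seq_along(out)) {
    lab <- out[i]
    if (startsWith(lab, "I-")) {
      ty <- substring(lab, 3)
      if (prev == "O" || substring(prev, 3) != ty) {
        if (strict) {
          stop_crf("invalid IOB2 continuation at position %d: %s after %s",
                   i, lab, prev, class = "crfvoter_bad_label")
        }
        out[i] <- paste0("B-", ty)
        changed <- TRUE
      }
    }
    prev <- out[i]
  }
  if (changed) {
    warning("repaired invalid IOB2 continuation(s) to B-", call. = FALSE)
  }
  out
}

empty_mentions <- function() {
  data.frame(doc_id = character(), sentence_index = integer(),
             start_token = integer(), end_token = integer(),
             entity_type = character(), stringsAsFactors = FALSE)
}

#' Encode entity spans as IOB2 tags
#'
#' @param sentence_length number of tokens.
#' @param mentions data.frame with `start_token`, `end_token` (0-based,
#'   half-open) and `entity_type`; mentions must lie within bounds and be
#'   pairwise non-overlapping.
#' @return character vector of `sentence_length` IOB2 tags.
#' @export
spans_to_iob <- function(sentence_length, mentions) {
  tags <- rep("O", sentence_length)
  if (is.null(mentions) || nrow(mentions) == 0L) return(tags)
  m <- mentions[order(mentions$start_token), , drop = FALSE]
  if (any(m$start_token < 0 | m$start_token >= m$end_token |
          m$end_token > sentence_length)) {
    stop_crf("mention span out of bounds for sentence of length %d",
             sentence_length, class = "crfvoter_span_bounds")
  }
  if (nrow(m) > 1L && any(m$start_token[-1] < m$end_token[-nrow(m)])) {
    i <- which(m$start_token[-1] < m$end_token[-nrow(m)])[1]
    stop_crf("overlapping mentions: [%d,%d) and [%d,%d)",
             m$start_token[i], m$end_token[i],
             m$start_token[i + 1], m$end_token[i + 1],
             class = "crfvoter_overlap")
  }
  for (i in seq_len(nrow(m))) {
    s <- m$start_token[i] + 1L
    e <- m$end_token[i]
    tags[s] <- paste0("B-", m$entity_type[i])
    if (e > s) tags[(s + 1L):e] <- paste0("I-", m$entity_type[i])
  }
  tags
}

#' Decode IOB2 tags into entity spans
#'
#' Exact inverse of [spans_to_iob()] on valid input; invalid continuations
#' are first repaired (see [repair_iob()]).
#'
#' @param labels character vector of IOB2 tags.
#' @param doc_id,sentence_index metadata attached to the returned mentions.
#' @return mention data.frame (possibly zero rows).
#' @export
iob_to_spans <- function(labels, doc_id = "", sentence_index = 0L) {
  labels <- suppressWarnings(repair_iob(labels))
  starts <- integer(0); ends <- integer(0); types <- character(0)
  open_type <- NULL; open_start <- NA_integer_
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (startsWith(lab, "B-") || lab == "O") {
      if (!is.null(open_type)) {
        starts <- c(starts, open_start); ends <- c(ends, i - 1L)
        types <- c(types, open_type)
        open_type <- NULL
      }
      if (startsWith(lab, "B-")) {
        open_type <- substring(lab, 3); open_start <- i - 1L
      }
    }
    # I- continues the open mention (repair guarantees type match)
  }
  if (!is.null(open_type)) {
    starts <- c(starts, open_start); ends <- c(ends, length(labels))
    types <- c(types, open_type)
  }
  data.frame(doc_id = rep(doc_id, length(starts)),
             sentence_index = rep(as.integer(sentence_index), length(starts)),
             start_token = starts, end_token = ends, entity_type = types,
             stringsAsFactors = FALSE)
}

#' All gold mentions of a corpus
#' @param corpus an `ner_corpus`.
#' @return mention data.frame across all documents and sentences.
#' @export
corpus_mentions <- function(corpus) {
  out <- list()
  for (doc in corpus$documents) {
    for (si in seq_along(doc$sentences)) {
      out[[length(out) + 1L]] <-
        iob_to_spans(doc$sentences[[si]]$labels, doc$doc_id, si - 1L)
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}

#' Mentions implied by a predicted tagging
#' @param corpus corpus giving doc/sentence structure.
#' @param tags list of tag vectors as returned by the package's taggers.
#' @return mention data.frame.
#' @export
tags_to_mentions <- function(corpus, tags) {
  out <- list(); k <- 0L
  for (doc in corpus$documents) {
    for (si in seq_along(doc$sentences)) {
      k <- k + 1L
      out[[k]] <- iob_to_spans(tags[[k]], doc$doc_id, si - 1L)
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}

#' Read a CoNLL-style TSV corpus
#'
#' One token per line: surface form, optional feature columns, IOB2 label
#' last, all tab-separated. A blank line ends a sentence; a line
#' `#doc <id>` starts a new document. Files without document markers yield
#' a single document `"doc1"`.
#'
#' @param path file path.
#' @return an `ner_corpus`.
#' @export
read_corpus_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_crf("no such file: %s", path, class = "crfvoter_io")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur_id <- NULL
  cur_sents <- list()
  rows <- list()
  ncol_seen <- NA_integer_
  auto <- 0L

  flush_sentence <- function() {
    if (length(rows) == 0L) return()
    mat <- do.call(rbind, rows)
    cols <- if (ncol(mat) > 2L) mat[, 2:(ncol(mat) - 1L), drop = FALSE]
    cur_sents[[length(cur_sents) + 1L]] <<-
      ner_sentence(mat[, 1L], labels = mat[, ncol(mat)], columns = cols)
    rows <<- list()
    ncol_seen <<- NA_integer_
  }
  flush_document <- function() {
    flush_sentence()
    if (is.null(cur_id) && length(cur_sents) == 0L) return()
    if (is.null(cur_id)) {
      auto <<- auto + 1L
      cur_id <<- paste0("doc", auto)
    }
    if (length(cur_sents) > 0L) {
      docs[[length(docs) + 1L]] <<- ner_document(cur_id, cur_sents)
    }
    cur_id <<- NULL
    cur_sents <<- list()
  }

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "#doc ")) {
      flush_document()
      cur_id <- sub("^#doc ", "", line)
      next
    }
    if (!nzchar(trimws(line))) { flush_sentence(); next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop_crf("line %d: expected at least 2 tab-separated fields", ln,
               class = "crfvoter_format")
    }
    if (is.na(ncol_seen)) ncol_seen <- length(fields)
    if (length(fields) != ncol_seen) {
      stop_crf("line %d: ragged column count (%d, sentence started with %d)",
               ln, length(fields), ncol_seen, class = "crfvoter_format")
    }
    rows[[length(rows) + 1L]] <- fields
  }
  flush_document()
  ner_corpus(docs)
}

#' Write a corpus as CoNLL-style TSV
#'
#' Inverse of [read_corpus_tsv()]: `#doc <id>` marker per document, blank
#' line after every sentence, label in the last column.
#'
#' @param corpus an `ner_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  out <- character(0)
  for (doc in corpus$documents) {
    out <- c(out, paste0("#doc ", doc$doc_id))
    for (s in doc$sentences) {
      body <- s$surface
      if (!is.null(s$columns)) {
        body <- apply(cbind(s$surface, s$columns), 1L, paste,
                      collapse = "\t")
      }
      out <- c(out, paste(body, s$labels, sep = "\t"), "")
    }
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_crf("cannot write %s: %s", path,
                                               conditionMessage(e),
                                               class = "crfvoter_io"))
  on.exit(close(con))
  if (length(out)) writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

# ---- document text and character offsets -----------------------------------

# A document's raw text is its tokens joined by single spaces, sentences
# included, in order. Offsets are 0-based half-open over that text.
document_text <- function(doc) {
  paste(unlist(lapply(doc$sentences, function(s) s$surface)), collapse = " ")
}

# data.frame of token character offsets within document_text(doc)
token_char_offsets <- function(doc) {
  surf <- unlist(lapply(doc$sentences, function(s) s$surface))
  lens <- nchar(surf)
  starts <- cumsum(c(0L, head(lens + 1L, -1L)))
  sent_idx <- rep(seq_along(doc$sentences) - 1L,
                  vapply(doc$sentences, length, integer(1)))
  tok_idx <- unlist(lapply(doc$sentences, function(s) seq_along(s$surface) - 1L))
  data.frame(sentence_index = sent_idx, token_index = tok_idx,
             start_char = starts, end_char = starts + lens)
}

#' Partition character-offset gold mentions into trainable and untrainable
#'
#' A mention whose character span aligns exactly with token boundaries
#' (starts at a token start, ends at a token end, within one sentence) is
#' trainable; a mention cutting inside a token (the "B-RafV600E" case,
#' where only a prefix of a fused token is annotated) cannot be expressed
#' in token-level IOB2 and is routed to the untrainable partition. Both
#' partitions together always equal the input. Untrainable mentions are
#' excluded from training labels but must stay in the evaluation gold
#' standard, where they count as errors.
#'
#' @param corpus an `ner_corpus`.
#' @param char_mentions data.frame with `doc_id`, `start_char`, `end_char`
#'   (0-based half-open over the document text, tokens joined by single
#'   spaces) and `entity_type`.
#' @return list with elements `trainable` (token-indexed mention
#'   data.frame) and `untrainable` (the input rows that do not align).
#' @export
filter_subtoken_mentions <- function(corpus, char_mentions) {
  ids <- vapply(corpus$documents, function(d) d$doc_id, character(1))
  train <- list(); untrain <- list()
  for (i in seq_len(nrow(char_mentions))) {
    row <- char_mentions[i, , drop = FALSE]
    di <- match(row$doc_id, ids)
    if (is.na(di)) {
      stop_crf("mention doc_id '%s' not in corpus", row$doc_id,
               class = "crfvoter_range")
    }
    doc <- corpus$documents[[di]]
    txt_len <- nchar(document_text(doc))
    if (row$start_char < 0 || row$end_char > txt_len ||
        row$start_char >= row$end_char) {
      stop_crf("mention [%d,%d) outside document text of length %d",
               row$start_char, row$end_char, txt_len,
               class = "crfvoter_range")
    }
    off <- token_char_offsets(doc)
    s <- which(off$start_char == row$start_char)
    e <- which(off$end_char == row$end_char)
    aligned <- length(s) == 1L && length(e) == 1L &&
      off$sentence_index[s] == off$sentence_index[e] && s <= e
    if (aligned) {
      train[[length(train) + 1L]] <- data.frame(
        doc_id = row$doc_id, sentence_index = off$sentence_index[s],
        start_token = off$token_index[s], end_token = off$token_index[e] + 1L,
        entity_type = row$entity_type, stringsAsFactors = FALSE)
    } else {
      untrain[[length(untrain) + 1L]] <- row
    }
  }
  list(
    trainable = if (length(train)) do.call(rbind, train) else empty_mentions(),
    untrainable = if (length(untrain)) do.call(rbind, untrain) else
      char_mentions[0, , drop = FALSE]
  )
}

#' Random document-level train/dev/test split
#'
#' Documents are shuffled deterministically under `seed` and partitioned
#' by floor-based sizes; leftover documents after flooring go to the
#' training split.
#'
#' @param corpus an `ner_corpus` with at least 3 documents.
#' @param ratios numeric length-3 vector of positive fractions summing to 1.
#' @param seed integer seed.
#' @return named list of three `ner_corpus` objects: `train`, `dev`, `test`.
#' @export
split_corpus <- function(corpus, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop_crf("ratios must be three positive fractions summing to 1",
             class = "crfvoter_ratios")
  }
  n <- length(corpus$documents)
  if (n < 3L) {
    stop_crf("cannot split %d document(s) three ways", n,
             class = "crfvoter_degenerate_split")
  }
  perm <- with_seed(seed, sample.int(n))
  n_dev <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_dev - n_test   # remainder biased into training
  idx <- list(train = perm[seq_len(n_train)],
              dev = perm[n_train + seq_len(n_dev)],
              test = perm[n_train + n_dev + seq_len(n_test)])
  lapply(idx, function(i) ner_corpus(corpus$documents[sort(i)]))
}

#' Split text on non-alphanumeric characters
#'
#' Helper mirroring the preprocessing variant in which tokens are split on
#' every non-alphanumeric character, keeping the separators as tokens
#' (whitespace is dropped).
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize_nonalnum <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9]", text))[[1]]
  toks[!grepl("^\\s$", toks)]
}
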