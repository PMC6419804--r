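# Linear-chain CRF: model container, exact inference and penalized
# maximum-likelihood training.
#
# The model scores a labeling y of a sentence x as
#   score(x, y) = sum_j [ emission(features_j, y_j) + transition(y_{j-1}, y_j) ]
# with a virtual START state supplying the j = 1 transition, and defines
#   P(y | x) = exp(score(x, y)) / Z_x,
# Z_x the sum of exp(score) over all labelings (forward recursion in log
# space). Transition features are label-pair indicators only (first-order
# chain). Unseen test-time features contribute 0.

#' Construct a CRF model from explicit weight matrices
#'
#' Mostly useful for testing and for small hand-built models; trained
#' models come from [crf_train()].
#'
#' @param labels ordered character vector of IOB2 tags (must contain
#'   `"O"`, no duplicates).
#' @param features character vector naming the emission feature rows.
#' @param emissions numeric matrix, `length(features)` x `length(labels)`.
#' @param transitions numeric matrix, `(length(labels)+1)` x
#'   `length(labels)`; the last row is the virtual START state.
#' @param penalty `"L2"` or `"L1"` (metadata for persistence).
#' @param cost_c positive penalty cost `c`.
#' @return an object of class `crf_model`.
#' @export
crf_model <- function(labels, features, emissions, transitions,
                      penalty = "L2", cost_c = 15) {
  labels <- as.character(labels)
  if (!"O" %in% labels || anyDuplicated(labels)) {
    stop_crf("label set must contain 'O' and have no duplicates",
             class = "crfvoter_label")
  }
  L <- length(labels)
  emissions <- as.matrix(emissions); transitions <- as.matrix(transitions)
  if (nrow(emissions) != length(features) || ncol(emissions) != L ||
      !all(dim(transitions) == c(L + 1L, L))) {
    stop_crf("weight matrix dimensions do not match labels/features",
             class = "crfvoter_dim")
  }
  if (!all(is.finite(emissions)) || !all(is.finite(transitions))) {
    stop_crf("weights must be finite", class = "crfvoter_weights")
  }
  structure(list(labels = labels, features = as.character(features),
                 W = unname(emissions), Tr = unname(transitions),
                 penalty = penalty, cost_c = cost_c, diagnostics = NULL),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model: %d labels, %d features, %s penalty, c = %g>\n",
              length(x$labels), length(x$features), x$penalty, x$cost_c))
  invisible(x)
}

# map one sentence's feature rows (list of character vectors) onto the
# model dictionary; unseen features are dropped (0 contribution)
encode_rows <- function(feature_rows, dict) {
  ids <- lapply(feature_rows, function(r) {
    m <- match(r, dict)
    as.integer(m[!is.na(m)] - 1L)
  })
  list(feats = as.integer(unlist(ids) %||% integer(0)),
       offs = as.integer(cumsum(c(0L, lengths(ids)))))
}

check_rows <- function(feature_rows) {
  if (!is.list(feature_rows) || length(feature_rows) == 0L) {
    stop_crf("feature_rows must be a non-empty list of character vectors",
             class = "crfvoter_empty")
  }
}

#' Unnormalized log-score of a labeling
#'
#' @param model a `crf_model`.
#' @param feature_rows list of character vectors, one per position.
#' @param labels character vector of tags, same length.
#' @return the sum of emission and transition weights along the labeling
#'   (the exponent of the model's conditional probability, before
#'   normalization).
#' @export
sequence_score <- function(model, feature_rows, labels) {
  check_rows(feature_rows)
  y <- match(labels, model$labels)
  if (anyNA(y)) {
    stop_crf("label '%s' not in model label set", labels[which(is.na(y))[1]],
             class = "crfvoter_label")
  }
  if (length(y) != length(feature_rows)) {
    stop_crf("labels and feature_rows differ in length",
             class = "crfvoter_length")
  }
  enc <- encode_rows(feature_rows, model$features)
  cpp_crf_score(enc$feats, enc$offs, as.integer(y - 1L), model$W, model$Tr)
}

#' Log partition function
#'
#' log of the sum over all labelings of exp(sequence score), computed by
#' the forward recursion with log-sum-exp stabilization.
#'
#' @inheritParams sequence_score
#' @return a real number.
#' @export
log_partition <- function(model, feature_rows) {
  check_rows(feature_rows)
  enc <- encode_rows(feature_rows, model$features)
  cpp_crf_logZ(enc$feats, enc$offs, model$W, model$Tr)
}

#' Viterbi decoding
#'
#' Returns a labeling maximizing the sequence score; ties are broken
#' toward the lowest label index at each backtracking step.
#'
#' @inheritParams sequence_score
#' @return character vector of tags.
#' @export
viterbi_decode <- function(model, feature_rows) {
  check_rows(feature_rows)
  enc <- encode_rows(feature_rows, model$features)
  path <- cpp_crf_viterbi(enc$feats, enc$offs, model$W, model$Tr)
  model$labels[path + 1L]
}

# ---- training --------------------------------------------------------------

pack_instances <- function(instances, labels) {
  dict <- sort(unique(unlist(lapply(instances, function(i)
    unlist(i$features)))))
  feats_list <- vector("list", length(instances))
  offs_list <- vector("list", length(instances))
  gold_list <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    enc <- encode_rows(instances[[i]]$features, dict)
    feats_list[[i]] <- enc$feats
    offs_list[[i]] <- enc$offs
    y <- match(instances[[i]]$labels, labels)
    if (anyNA(y)) {
      stop_crf("training label outside declared label set",
               class = "crfvoter_label")
    }
    gold_list[[i]] <- as.integer(y - 1L)
  }
  list(dict = dict, feats = feats_list, offs = offs_list, gold = gold_list)
}

#' Penalized log-likelihood objective closure
#'
#' Builds the negated penalized objective and its analytic gradient over a
#' flat parameter vector `c(W, Tr)`. The maximized quantity is
#' `sum log P(y|x) - penalty` with penalty `(1/c) * ||lambda||_1` (L1) or
#' `(1/(2c)) * ||lambda||_2^2` (L2); the returned functions are its
#' negation, suitable for minimizers and for finite-difference checks.
#'
#' @param instances list of training instances, each a list with
#'   `features` (list of character vectors) and `labels` (tags).
#' @param penalty `"L2"` or `"L1"`.
#' @param cost_c positive cost `c`.
#' @param labels optional explicit label set; defaults to the labels seen.
#' @return list with `fn`, `gr`, `fn_smooth`, `gr_smooth` (unpenalized
#'   part for L1 solvers), `n_par`, `labels`, `dict`, and `unpack()`.
#' @export
crf_objective <- function(instances, penalty = "L2", cost_c = 15,
                          labels = NULL) {
  if (length(instances) == 0L) {
    stop_crf("empty training set", class = "crfvoter_empty")
  }
  if (!is.numeric(cost_c) || cost_c <= 0) {
    stop_crf("cost_c must be positive", class = "crfvoter_config")
  }
  penalty <- match.arg(penalty, c("L2", "L1"))
  if (is.null(labels)) {
    seen <- unique(unlist(lapply(instances, `[[`, "labels")))
    labels <- c("O", sort(setdiff(seen, "O")))
  }
  L <- length(labels)
  packed <- pack_instances(instances, labels)
  nF <- length(packed$dict)
  nW <- nF * L
  n_par <- nW + (L + 1L) * L
  unpack <- function(theta) {
    list(W = matrix(theta[seq_len(nW)], nrow = nF, ncol = L),
         Tr = matrix(theta[nW + seq_len((L + 1L) * L)], nrow = L + 1L))
  }
  eval_ll <- function(theta, want_grad) {
    m <- unpack(theta)
    cpp_crf_loglik_grad(packed$feats, packed$offs, packed$gold,
                        m$W, m$Tr, want_grad)
  }
  fn_smooth <- function(theta) -eval_ll(theta, FALSE)$loglik
  gr_smooth <- function(theta) {
    r <- eval_ll(theta, TRUE)
    -c(as.numeric(r$gW), as.numeric(r$gT))
  }
  pen <- function(theta) {
    if (penalty == "L2") sum(theta^2) / (2 * cost_c)
    else sum(abs(theta)) / cost_c
  }
  dpen <- function(theta) {
    if (penalty == "L2") theta / cost_c else sign(theta) / cost_c
  }
  list(
    fn = function(theta) fn_smooth(theta) + pen(theta),
    gr = function(theta) gr_smooth(theta) + dpen(theta),
    fn_smooth = fn_smooth, gr_smooth = gr_smooth,
    penalty = penalty, cost_c = cost_c,
    n_par = n_par, labels = labels, dict = packed$dict, unpack = unpack
  )
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# FISTA with backtracking for the L1-penalized objective
fista_l1 <- function(obj, max_iter, tol) {
  th <- numeric(obj$n_par)
  z <- th; tk <- 1
  Lc <- 1
  f_prev <- obj$fn(th)
  pen_scale <- 1 / obj$cost_c
  iter_used <- 0L
  for (it in seq_len(max_iter)) {
    iter_used <- it
    g <- obj$gr_smooth(z)
    fz <- obj$fn_smooth(z)
    repeat {
      cand <- soft_threshold(z - g / Lc, pen_scale / Lc)
      d <- cand - z
      if (obj$fn_smooth(cand) <=
          fz + sum(g * d) + (Lc / 2) * sum(d * d) + 1e-12) break
      Lc <- Lc * 2
      if (Lc > 1e12) break
    }
    th_new <- cand
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- th_new + ((tk - 1) / t_new) * (th_new - th)
    th <- th_new; tk <- t_new
    f_cur <- obj$fn(th)
    if (!is.finite(f_cur)) {
      stop_crf("training objective diverged (non-finite)",
               class = "crfvoter_divergence")
    }
    if (abs(f_prev - f_cur) < tol * max(1, abs(f_prev))) break
    f_prev <- f_cur
  }
  list(par = th, value = obj$fn(th), iterations = iter_used)
}

#' Train a linear-chain CRF
#'
#' Maximizes the penalized conditional log-likelihood. L2 uses
#' limited-memory BFGS with the analytic gradient; L1 uses a proximal
#' gradient (FISTA) loop with soft-thresholding. Convergence: relative
#' objective change below `tol` or `max_iter` iterations.
#'
#' @inheritParams crf_objective
#' @param max_iter iteration cap (default 300).
#' @param tol relative convergence tolerance (default 1e-6).
#' @return a `crf_model` whose `diagnostics` record iterations, the final
#'   penalized objective and a convergence flag.
#' @export
crf_train <- function(instances, penalty = "L2", cost_c = 15,
                      max_iter = 300L, tol = 1e-6, labels = NULL) {
  obj <- crf_objective(instances, penalty, cost_c, labels)
  if (obj$penalty == "L2") {
    res <- optim(numeric(obj$n_par), fn = obj$fn, gr = obj$gr,
                 method = "L-BFGS-B",
                 control = list(maxit = max_iter,
                                factr = tol / .Machine$double.eps))
    if (!is.finite(res$value)) {
      stop_crf("training objective diverged (non-finite)",
               class = "crfvoter_divergence")
    }
    par <- res$par
    diag <- list(iterations = res$counts[["function"]],
                 objective = -res$value, converged = res$convergence == 0)
  } else {
    res <- fista_l1(obj, max_iter, tol)
    par <- res$par
    diag <- list(iterations = res$iterations, objective = -res$value,
                 converged = res$iterations < max_iter)
  }
  m <- obj$unpack(par)
  model <- crf_model(obj$labels, obj$dict, m$W, m$Tr,
                     penalty = obj$penalty, cost_c = cost_c)
  model$diagnostics <- diag
  model
}

# ---- persistence -----------------------------------------------------------

#' Save a CRF model (JSON header + TSV weight table)
#'
#' Weights are serialized with 17 significant digits, which round-trips
#' IEEE doubles exactly, so [read_crf_model()] reloads bit-identically.
#'
#' @param model a `crf_model`.
#' @param path output path prefix; writes `<path>.json` and `<path>.tsv`.
#' @return `path`, invisibly.
#' @export
write_crf_model <- function(model, path) {
  header <- list(labels = model$labels, penalty = model$penalty,
                 cost_c = model$cost_c, n_features = length(model$features))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  L <- length(model$labels)
  em <- sprintf("E\t%s\t%s\t%.17g",
                rep(model$features, times = L),
                rep(model$labels, each = length(model$features)),
                as.numeric(model$W))
  from <- c(model$labels, "<START>")
  tr <- sprintf("T\t%s\t%s\t%.17g",
                rep(from, times = L),
                rep(model$labels, each = L + 1L),
                as.numeric(model$Tr))
  writeLines(c(em, tr), paste0(path, ".tsv"), useBytes = TRUE)
  invisible(path)
}

#' Load a CRF model saved by [write_crf_model()]
#' @param path path prefix used at save time.
#' @return a `crf_model`.
#' @export
read_crf_model <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rows <- strsplit(readLines(paste0(path, ".tsv")), "\t", fixed = TRUE)
  kind <- vapply(rows, `[`, character(1), 1L)
  a <- vapply(rows, `[`, character(1), 2L)
  b <- vapply(rows, `[`, character(1), 3L)
  wt <- as.numeric(vapply(rows, `[`, character(1), 4L))
  labels <- header$labels
  L <- length(labels)
  features <- unique(a[kind == "E"])
  W <- matrix(0, length(features), L)
  ei <- kind == "E"
  W[cbind(match(a[ei], features), match(b[ei], labels))] <- wt[ei]
  from <- c(labels, "<START>")
  Tr <- matrix(0, L + 1L, L)
  ti <- kind == "T"
  Tr[cbind(match(a[ti], from), match(b[ti], labels))] <- wt[ti]
  crf_model(labels, features, W, Tr, header$penalty, header$cost_c)
}
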