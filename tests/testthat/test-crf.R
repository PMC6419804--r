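# crf: scoring, partition function, Viterbi, training and persistence,
# checked against exhaustive enumeration and finite differences.

test_that("sequence_score closed forms", {
  labs <- c("O", "B-X")
  m0 <- crf_model(labs, c("f", "b"), matrix(0, 2, 2), matrix(0, 3, 2))
  rows <- list(c("f"), c("b"))
  for (y in enumerate_labelings(labs, 2L)) {
    expect_equal(sequence_score(m0, rows, y), 0)
  }
  W <- matrix(0, 2, 2); W[1, 2] <- 1.5   # weight on (f, B-X)
  m1 <- crf_model(labs, c("f", "b"), W, matrix(0, 3, 2))
  expect_equal(sequence_score(m1, list("f"), "B-X"), 1.5)
  expect_equal(sequence_score(m1, list("f"), "O"), 0)
  expect_error(sequence_score(m1, list("f"), "B-Z"),
               class = "crfvoter_label")
})

test_that("log_partition closed forms and stability", {
  labs <- c("O", "B-X")
  W <- matrix(c(2, -1), 1, 2)       # emission: s1 = 2 for O, s2 = -1 for B-X
  m <- crf_model(labs, "f", W, matrix(0, 3, 2))
  expect_equal(log_partition(m, list("f")), log(exp(2) + exp(-1)))
  # all-zero weights: n * log(|Y|)
  m0 <- crf_model(labs, "f", matrix(0, 1, 2), matrix(0, 3, 2))
  for (n in 1:4) {
    expect_equal(log_partition(m0, rep(list("f"), n)), n * log(2))
  }
})

test_that("inference agrees with exhaustive enumeration on random models", {
  set.seed(31)
  for (i in 1:40) {
    m <- random_tiny_model(n_labels = sample(2:4, 1L))
    n <- sample(1:4, 1L)
    rows <- random_feature_rows(m, n)
    ys <- enumerate_labelings(m$labels, n)
    scores <- vapply(ys, function(y) bf_score(m, rows, y), numeric(1))
    expect_equal(log_partition(m, rows), log(sum(exp(scores))),
                 tolerance = 1e-10)
    # probabilities sum to one
    expect_equal(sum(exp(scores - log_partition(m, rows))), 1,
                 tolerance = 1e-10)
    # per-sequence probability matches brute-force normalization
    y1 <- ys[[1]]
    expect_equal(exp(sequence_score(m, rows, y1) - log_partition(m, rows)),
                 exp(scores[1]) / sum(exp(scores)), tolerance = 1e-10)
    expect_viterbi_optimal(m, rows, ys, scores)
  }
})

test_that("viterbi follows forced paths and breaks ties to lowest index", {
  labs <- c("O", "B-X", "I-X")
  feats <- c("p1", "p2", "p3")
  W <- matrix(0, 3, 3)
  W[1, 2] <- 5; W[2, 3] <- 5; W[3, 1] <- 5  # p1->B-X, p2->I-X, p3->O
  m <- crf_model(labs, feats, W, matrix(0, 4, 3))
  expect_equal(viterbi_decode(m, list("p1", "p2", "p3")),
               c("B-X", "I-X", "O"))
  m0 <- crf_model(labs, feats, matrix(0, 3, 3), matrix(0, 4, 3))
  expect_equal(viterbi_decode(m0, list("p1", "p2", "p3")),
               c("O", "O", "O"))  # all-first-label path under total ties
})

test_that("viterbi beats 100 random labelings", {
  set.seed(32)
  m <- random_tiny_model(4, 5)
  rows <- random_feature_rows(m, 6L)
  best <- sequence_score(m, rows, viterbi_decode(m, rows))
  for (i in 1:100) {
    y <- sample(m$labels, 6L, replace = TRUE)
    expect_gte(best, sequence_score(m, rows, y))
  }
})

test_that("analytic gradients match finite differences (L2 and L1 smooth part)", {
  set.seed(33)
  insts <- lapply(1:4, function(i) {
    n <- sample(2:4, 1L)
    list(features = lapply(seq_len(n), function(j)
      c("b", sample(c("u", "v", "w"), 2L))),
      labels = sample(c("O", "B-X"), n, replace = TRUE))
  })
  for (pen in c("L2", "L1")) {
    obj <- crf_objective(insts, pen, cost_c = 3)
    th <- rnorm(obj$n_par, sd = 0.4)
    th[abs(th) < 0.05] <- 0.1   # keep clear of the L1 kink
    fn <- if (pen == "L2") obj$fn else obj$fn_smooth
    gr <- if (pen == "L2") obj$gr else obj$gr_smooth
    g <- gr(th)
    h <- 1e-6
    num <- vapply(seq_along(th), function(i) {
      e <- replace(numeric(length(th)), i, h)
      (fn(th + e) - fn(th - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - num) / pmax(abs(num), 1e-6)), 1e-5)
  }
})

test_that("training fits a separable corpus and c -> 0 shrinks weights", {
  insts <- separable_instances(50L, seed = 41)
  model <- crf_train(insts, penalty = "L2", cost_c = 15)
  acc <- mean(unlist(lapply(insts, function(i)
    viterbi_decode(model, i$features) == i$labels)))
  expect_equal(acc, 1.0)
  expect_true(model$diagnostics$converged)

  tiny <- crf_train(insts[1:10], penalty = "L2", cost_c = 1e-6)
  expect_lt(max(abs(tiny$W)), 1e-3)
  expect_lt(max(abs(tiny$Tr)), 1e-3)
})

test_that("regularization path is monotone in c", {
  insts <- separable_instances(20L, seed = 43)
  norms <- vapply(c(0.1, 1, 10), function(cc) {
    m <- crf_train(insts, "L2", cc)
    sqrt(sum(m$W^2) + sum(m$Tr^2))
  }, numeric(1))
  expect_true(all(diff(norms) > 0))
})

test_that("L1 training works and induces exact zeros", {
  insts <- separable_instances(30L, seed = 44)
  model <- crf_train(insts, penalty = "L1", cost_c = 2, max_iter = 400)
  acc <- mean(unlist(lapply(insts, function(i)
    viterbi_decode(model, i$features) == i$labels)))
  expect_gt(acc, 0.95)
  # a stronger penalty (smaller c) zeroes some weights exactly
  sparse <- crf_train(insts, penalty = "L1", cost_c = 0.3, max_iter = 400)
  expect_gt(sum(sparse$W == 0) + sum(sparse$Tr == 0), 0)
})

test_that("models persist to JSON + TSV and reload bit-exactly", {
  set.seed(45)
  m <- random_tiny_model(3, 5)
  path <- file.path(tempdir(), "crfmodel")
  write_crf_model(m, path)
  back <- read_crf_model(path)
  expect_identical(back$labels, m$labels)
  expect_identical(back$W, m$W)
  expect_identical(back$Tr, m$Tr)
  rows <- random_feature_rows(m, 3L)
  expect_identical(log_partition(back, rows), log_partition(m, rows))
})

test_that("unseen features contribute zero at test time", {
  set.seed(46)
  m <- random_tiny_model(2, 3)
  rows <- list(c("f1", "NEVER-SEEN"), "f2")
  rows_clean <- list("f1", "f2")
  expect_equal(log_partition(m, rows), log_partition(m, rows_clean))
})
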