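# hyperopt: grid enumeration, random sampling, TPE splitting/suggestion
# and the optimization driver.

quad_objective <- function(cfg) -(cfg$x - 0.3)^2

test_that("grid search enumerates the full space exactly once", {
  res <- grid_search(crfpp_space(), function(cfg) {
    if (identical(cfg$a, "CRF-L2") && cfg$c == 15) 0.69 else 0.5
  })
  expect_length(res$trials, 20L)
  cfgs <- lapply(res$trials, `[[`, "config")
  expect_equal(anyDuplicated(vapply(cfgs, function(c)
    paste(c$c, c$a), character(1))), 0L)
  expect_equal(res$best$config$c, 15)
  expect_equal(res$best$metric,
               max(vapply(res$trials, `[[`, numeric(1), "metric")))

  single <- param_space(x = dim_cat("only"))
  res1 <- grid_search(single, function(cfg) 0.4)
  expect_length(res1$trials, 1L)
  expect_equal(res1$best$trial_index, 1L)

  expect_error(grid_search(param_space(x = dim_float(0, 1)), identity),
               class = "crfvoter_unsupported_space")
})

test_that("grid ties go to the lowest trial index", {
  sp <- param_space(x = dim_cat(c("a", "b", "c")))
  res <- grid_search(sp, function(cfg) 1)
  expect_equal(res$best$trial_index, 1L)
})

test_that("random search is deterministic, uniform and budgeted", {
  sp <- param_space(x = dim_float(0, 1))
  r1 <- random_search(sp, quad_objective, budget = 1L, seed = 3)
  expect_length(r1$trials, 1L)
  r2 <- random_search(sp, quad_objective, budget = 25L, seed = 9)
  r3 <- random_search(sp, quad_objective, budget = 25L, seed = 9)
  expect_identical(r2, r3)

  xs <- crfvoter:::with_seed(123, replicate(10000, {
    crfvoter:::sample_config(sp)$x
  }))
  ks <- max(abs(sort(xs) - (seq_along(xs) - 0.5) / length(xs)))
  expect_lt(ks, 1.63 / sqrt(10000))  # KS 1% critical value
})

make_trials <- function(metrics) {
  lapply(seq_along(metrics), function(i)
    crfvoter:::new_trial(list(x = i / length(metrics)), metrics[i], i))
}

test_that("tpe_split takes the top gamma fraction, ties by index", {
  tr <- make_trials(c(0.1, 0.9, 0.3, 0.8, 0.2, 0.5, 0.4, 0.6, 0.7, 0.05))
  sp <- tpe_split(tr, gamma = 0.2)
  expect_equal(sort(vapply(sp$good, `[[`, numeric(1), "metric")),
               c(0.8, 0.9))
  expect_length(sp$bad, 8L)
  # conservation
  expect_setequal(c(vapply(sp$good, `[[`, numeric(1), "trial_index"),
                    vapply(sp$bad, `[[`, numeric(1), "trial_index")),
                  1:10)
  # all-equal metrics: both groups non-empty, earliest trials good
  tre <- make_trials(rep(0.5, 6))
  spe <- tpe_split(tre, gamma = 0.3)
  expect_equal(vapply(spe$good, `[[`, numeric(1), "trial_index"), c(1, 2))
  expect_error(tpe_split(tre[1], 0.2), class = "crfvoter_history")
})

test_that("tpe_suggest: identical groups give EI = 1, first draw returned", {
  sp <- param_space(x = dim_cat(c("a", "b")))
  # good and bad groups contain identical configurations
  tr <- list(crfvoter:::new_trial(list(x = "a"), 0.9, 1),
             crfvoter:::new_trial(list(x = "b"), 0.8, 2),
             crfvoter:::new_trial(list(x = "a"), 0.2, 3),
             crfvoter:::new_trial(list(x = "b"), 0.1, 4))
  st <- tpe_settings(gamma = 0.5, n_startup = 2, n_candidates = 8)
  first <- crfvoter:::with_seed(7, tpe_suggest(tr, sp, tpe_settings(
    gamma = 0.5, n_startup = 2, n_candidates = 1)))
  many <- crfvoter:::with_seed(7, tpe_suggest(tr, sp, st))
  expect_identical(many, first)
})

test_that("tpe_suggest prefers a category seen only in the good group", {
  sp <- param_space(x = dim_cat(c("A", "B", "C")))
  tr <- list(crfvoter:::new_trial(list(x = "A"), 0.9, 1),
             crfvoter:::new_trial(list(x = "A"), 0.8, 2),
             crfvoter:::new_trial(list(x = "B"), 0.2, 3),
             crfvoter:::new_trial(list(x = "C"), 0.1, 4),
             crfvoter:::new_trial(list(x = "B"), 0.15, 5))
  d <- tpe_densities(tr, sp, gamma = 0.4)
  # good group = {A, A}: smoothed l(A) = 3/5; bad never saw A: g(A) = 1/6
  expect_equal(d$l$x$probs[[1]], 3 / 5)
  expect_equal(d$g$x$probs[[1]], 1 / 6)
  expect_gt(d$l$x$probs[[1]], d$g$x$probs[[1]])
  sug <- crfvoter:::with_seed(1, tpe_suggest(tr, sp, tpe_settings(
    gamma = 0.4, n_startup = 2, n_candidates = 24)))
  expect_identical(sug$x, "A")
})

test_that("driver: trajectory monotone, failures scored 0, grid budget", {
  sp <- param_space(x = dim_float(0, 1))
  rep <- optimize_params(sp, quad_objective, method = "random",
                         budget = 30L, seed = 5)
  expect_length(rep$trials, 30L)
  expect_true(all(diff(rep$trajectory) >= 0))
  expect_equal(rep$best$metric, max(rep$trajectory))

  flaky <- function(cfg) if (cfg$x < 0.5) stop("boom") else cfg$x
  w <- capture_warnings(
    repf <- optimize_params(sp, flaky, method = "random", budget = 10L,
                            seed = 8))
  expect_true(any(grepl("failed", w)))
  ms <- vapply(repf$trials, `[[`, numeric(1), "metric")
  expect_true(any(ms == 0))

  repg <- optimize_params(crfpp_space(), function(cfg) 0.5,
                          method = "grid")
  expect_length(repg$trials, 20L)
})

test_that("TPE with n_startup >= budget is bit-identical to random search", {
  sp <- param_space(x = dim_float(0, 1), k = dim_int(1, 5))
  a <- optimize_params(sp, quad_objective, method = "random", budget = 15L,
                       seed = 21)
  b <- optimize_params(sp, quad_objective, method = "tpe", budget = 15L,
                       seed = 21,
                       settings = tpe_settings(n_startup = 15L))
  expect_identical(a$trials, b$trials)
})

test_that("spaces and trial logs round-trip through JSON", {
  sp <- param_space(c = dim_cat(c(0.6, 1)), n = dim_int(1, 4),
                    x = dim_float(0, 2))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(c = list(type = "cat", values = c(0.6, 1)),
         n = list(type = "int", low = 1, high = 4),
         x = list(type = "float", low = 0, high = 2)),
    path, auto_unbox = TRUE, digits = NA)
  sp2 <- read_param_space(path)
  expect_equal(names(sp2$dims), names(sp$dims))
  expect_equal(sp2$dims$n$high, 4L)

  rep <- optimize_params(sp, function(cfg) cfg$x / 2, method = "random",
                         budget = 5L, seed = 2)
  log <- tempfile(fileext = ".jsonl")
  write_trials_jsonl(rep, log)
  lines <- readLines(log)
  expect_length(lines, 5L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_named(parsed, c("trial_index", "metric", "config"))
})
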