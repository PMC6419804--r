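# Hyperparameter search: exhaustive grid, random sampling, and a
# tree-structured Parzen estimator (TPE).
#
# The driver maximizes the objective (a validation metric such as F1);
# the classical formulation minimizes a loss, so callers optimizing a
# loss should negate it once. TPE splits the trial history into a "good"
# group (metrics above the (1-gamma) quantile) and a "bad" group, fits a
# density l(x) to good and g(x) to bad configurations per dimension,
# samples candidates from l and proposes the candidate maximizing the
# expected-improvement ratio EI(x) = l(x)/g(x). Conditional (truly
# tree-structured) spaces are not implemented: all supported spaces are
# flat products of independent dimensions.

#' Parameter space
#'
#' @param ... named dimensions built with [dim_cat()], [dim_int()] or
#'   [dim_float()].
#' @return an object of class `param_space`.
#' @export
param_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L || is.null(names(dims)) ||
      any(!nzchar(names(dims))) || anyDuplicated(names(dims))) {
    stop_crf("param_space needs uniquely named dimensions",
             class = "crfvoter_config")
  }
  ok <- vapply(dims, function(d) inherits(d, "space_dim"), logical(1))
  if (!all(ok)) {
    stop_crf("dimensions must be dim_cat/dim_int/dim_float",
             class = "crfvoter_config")
  }
  structure(list(dims = dims), class = "param_space")
}

#' @rdname param_space
#' @param values finite vector of categorical values.
#' @export
dim_cat <- function(values) {
  if (length(values) == 0L) {
    stop_crf("empty categorical domain", class = "crfvoter_config")
  }
  structure(list(type = "cat", values = values),
            class = c("space_dim"))
}

#' @rdname param_space
#' @param low,high inclusive integer bounds / finite real bounds.
#' @export
dim_int <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  if (is.na(low) || is.na(high) || high < low) {
    stop_crf("invalid integer range", class = "crfvoter_config")
  }
  structure(list(type = "int", low = low, high = high),
            class = c("space_dim"))
}

#' @rdname param_space
#' @export
dim_float <- function(low, high) {
  if (!is.finite(low) || !is.finite(high) || high <= low) {
    stop_crf("continuous bounds must be finite with high > low",
             class = "crfvoter_config")
  }
  structure(list(type = "float", low = low, high = high),
            class = c("space_dim"))
}

# one uniform draw from the space, consuming the current RNG stream;
# dimensions are sampled in declaration order
sample_config <- function(space) {
  out <- lapply(space$dims, function(d) {
    switch(d$type,
      cat = d$values[[sample.int(length(d$values), 1L)]],
      int = sample.int(d$high - d$low + 1L, 1L) + d$low - 1L,
      float = runif(1L, d$low, d$high))
  })
  out
}

new_trial <- function(config, metric, trial_index) {
  structure(list(config = config, metric = metric,
                 trial_index = trial_index), class = "crf_trial")
}

grid_configs <- function(space) {
  doms <- lapply(space$dims, function(d) {
    if (d$type == "float") {
      stop_crf("grid search requires finite dimensions; discretize '%s'",
               "continuous dimension", class = "crfvoter_unsupported_space")
    }
    if (d$type == "int") as.list(d$low:d$high) else as.list(d$values)
  })
  # lexicographic in dimension order: first dimension varies slowest
  idx <- do.call(expand.grid,
                 c(rev(lapply(doms, seq_along)), KEEP.OUT.ATTRS = FALSE))
  idx <- idx[, rev(seq_along(doms)), drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    setNames(lapply(seq_along(doms), function(d) doms[[d]][[idx[r, d]]]),
             names(space$dims))
  })
}

run_objective <- function(objective, config, trial_index) {
  metric <- tryCatch(objective(config), error = function(e) {
    warning(sprintf("trial %d failed (%s); scored 0", trial_index,
                    conditionMessage(e)), call. = FALSE)
    0
  })
  new_trial(config, as.numeric(metric), trial_index)
}

#' Exhaustive grid search
#'
#' Evaluates every configuration of a finite space exactly once, in
#' lexicographic dimension order; continuous dimensions are rejected.
#'
#' @param space a [param_space()] with finite dimensions only.
#' @param objective function(config) -> metric (maximized). A failing
#'   objective scores the trial 0 with a warning.
#' @return list with `best` (max-metric trial, ties to the lowest trial
#'   index) and `trials` (all trials).
#' @export
grid_search <- function(space, objective) {
  configs <- grid_configs(space)
  trials <- lapply(seq_along(configs), function(i)
    run_objective(objective, configs[[i]], i))
  metrics <- vapply(trials, `[[`, numeric(1), "metric")
  list(best = trials[[which.max(metrics)]], trials = trials)
}

#' Random search
#'
#' Samples each dimension independently and uniformly; deterministic
#' given `seed`.
#'
#' @inheritParams grid_search
#' @param budget number of trials (>= 1).
#' @param seed integer seed.
#' @return list with `best` and `trials`.
#' @export
random_search <- function(space, objective, budget, seed = 1L) {
  stopifnot(budget >= 1L)
  trials <- with_seed(seed, {
    lapply(seq_len(budget), function(i)
      run_objective(objective, sample_config(space), i))
  })
  metrics <- vapply(trials, `[[`, numeric(1), "metric")
  list(best = trials[[which.max(metrics)]], trials = trials)
}

#' Split a trial history into good and bad groups
#'
#' The good group holds the trials with the highest metrics — those above
#' the (1-gamma) quantile, i.e. `ceiling(gamma * n)` trials (at least one,
#' never all); ties are broken by trial index so both groups are
#' non-empty and the split is deterministic.
#'
#' @param trials list of trials (from a search or [optimize_params()]).
#' @param gamma good-group fraction in (0, 1).
#' @return list with `good` and `bad` trial lists.
#' @export
tpe_split <- function(trials, gamma = 0.25) {
  n <- length(trials)
  if (n < 2L) {
    stop_crf("need at least 2 trials to split", class = "crfvoter_history")
  }
  metrics <- vapply(trials, `[[`, numeric(1), "metric")
  idx <- vapply(trials, `[[`, numeric(1), "trial_index")
  ord <- order(-metrics, idx)
  n_good <- max(1L, min(n - 1L, as.integer(ceiling(gamma * n))))
  list(good = trials[ord[seq_len(n_good)]],
       bad = trials[ord[(n_good + 1L):n]])
}

#' TPE settings
#'
#' Defaults follow common TPE practice: `gamma = 0.25`, 20 random startup
#' trials, 24 candidate draws per iteration, per-point neighbor-distance
#' kernel bandwidths with a uniform prior component.
#'
#' @param gamma good-group fraction in (0,1).
#' @param n_startup random trials before model-based suggestions.
#' @param n_candidates candidate draws per suggestion.
#' @param bandwidth_rule kernel bandwidth rule: `"neighbor"` (default,
#'   per-point nearest-neighbor widths with a uniform prior component) or
#'   `"silverman"` (global Silverman width).
#' @return a `tpe_settings` object.
#' @export
tpe_settings <- function(gamma = 0.25, n_startup = 20L, n_candidates = 24L,
                         bandwidth_rule = c("neighbor", "silverman")) {
  stopifnot(gamma > 0, gamma < 1, n_startup >= 1L, n_candidates >= 1L)
  bandwidth_rule <- match.arg(bandwidth_rule)
  structure(list(gamma = gamma, n_startup = as.integer(n_startup),
                 n_candidates = as.integer(n_candidates),
                 bandwidth_rule = bandwidth_rule), class = "tpe_settings")
}

# per-dimension density description fitted to one trial group.
#
# Continuous/integer dimensions use a Parzen mixture over the observed
# values plus one uniform-over-range prior component (weight 1/(k+1)).
# Bandwidths: "neighbor" (default) gives each kernel the distance to its
# nearest observed neighbors, clipped to [range/50, range] — the widths
# adapt to the local point density, so a tight cluster of past proposals
# cannot collapse the estimator and freeze the search; "silverman" uses
# the classic 1.06 * sd * k^(-1/5) global width.
fit_dim_density <- function(dim, values, rule = "neighbor") {
  if (dim$type == "cat") {
    counts <- vapply(dim$values, function(v)
      sum(vapply(values, identical, logical(1), v)), numeric(1))
    probs <- (counts + 1) / (length(values) + length(dim$values))
    list(type = "cat", probs = probs)
  } else {
    x <- as.numeric(unlist(values))
    rng <- dim$high - dim$low
    if (rule == "silverman") {
      s <- sd(x)
      if (length(x) < 2L || !is.finite(s) || s == 0) s <- rng / 4
      bw <- rep(max(1.06 * s * length(x)^(-1 / 5), rng * 1e-3), length(x))
    } else {
      if (length(x) < 2L) {
        bw <- rng / 2
      } else {
        o <- order(x)
        d <- pmax(c(diff(x[o]), Inf), c(Inf, diff(x[o])))
        bw <- numeric(length(x))
        bw[o] <- pmin(pmax(d, rng / 50), rng)
      }
    }
    list(type = dim$type, centers = x, bw = bw,
         low = dim$low, high = dim$high)
  }
}

eval_dim_density <- function(dim, dens, value) {
  if (dens$type == "cat") {
    i <- which(vapply(dim$values, identical, logical(1), value))
    dens$probs[i]
  } else {
    k <- length(dens$centers)
    rng <- dens$high - dens$low
    kern <- sum(dnorm(as.numeric(value), mean = dens$centers,
                      sd = dens$bw))
    (kern + 1 / rng) / (k + 1)
  }
}

sample_from_density <- function(dim, dens) {
  if (dens$type == "cat") {
    dim$values[[sample.int(length(dim$values), 1L, prob = dens$probs)]]
  } else {
    k <- length(dens$centers)
    x <- if (runif(1L) < 1 / (k + 1)) {
      runif(1L, dens$low, dens$high)   # prior component
    } else {
      j <- sample.int(k, 1L)
      min(max(rnorm(1L, dens$centers[j], dens$bw[j]), dens$low),
          dens$high)
    }
    if (dens$type == "int") as.integer(round(x)) else x
  }
}

#' Fitted TPE densities for inspection
#'
#' @param trials trial history (>= 2 trials).
#' @param space the [param_space()].
#' @param gamma good-group fraction.
#' @param rule bandwidth rule (see [tpe_settings()]).
#' @return list with per-dimension density descriptions `l` (good) and
#'   `g` (bad).
#' @export
tpe_densities <- function(trials, space, gamma = 0.25,
                          rule = "neighbor") {
  sp <- tpe_split(trials, gamma)
  per_dim <- function(group) {
    lapply(names(space$dims), function(nm)
      fit_dim_density(space$dims[[nm]],
                      lapply(group, function(t) t$config[[nm]]), rule))
  }
  list(l = setNames(per_dim(sp$good), names(space$dims)),
      g = setNames(per_dim(sp$bad), names(space$dims)))
}

#' Propose the next configuration by TPE
#'
#' With fewer than `n_startup` trials this is a single uniform random
#' draw; otherwise `n_candidates` candidates are sampled from the
#' good-group density l and the candidate maximizing EI(x) = l(x)/g(x)
#' is returned (ties keep the earliest draw).
#'
#' @param trials trial history.
#' @param space the [param_space()].
#' @param settings a [tpe_settings()] object.
#' @return a configuration (named list).
#' @export
tpe_suggest <- function(trials, space, settings = tpe_settings()) {
  if (length(space$dims) == 0L) {
    stop_crf("empty parameter space", class = "crfvoter_config")
  }
  if (length(trials) < settings$n_startup) {
    return(sample_config(space))
  }
  dens <- tpe_densities(trials, space, settings$gamma,
                        settings$bandwidth_rule)
  nms <- names(space$dims)
  cands <- vector("list", settings$n_candidates)
  ei <- numeric(settings$n_candidates)
  for (k in seq_len(settings$n_candidates)) {
    cfg <- setNames(lapply(nms, function(nm)
      sample_from_density(space$dims[[nm]], dens$l[[nm]])), nms)
    log_ei <- 0
    for (nm in nms) {
      lv <- eval_dim_density(space$dims[[nm]], dens$l[[nm]], cfg[[nm]])
      gv <- eval_dim_density(space$dims[[nm]], dens$g[[nm]], cfg[[nm]])
      log_ei <- log_ei + log(max(lv, 1e-300)) - log(max(gv, 1e-300))
    }
    cands[[k]] <- cfg
    ei[k] <- log_ei
  }
  cands[[which.max(ei)]]
}

#' Hyperparameter optimization driver
#'
#' Runs grid, random or TPE search and collects the full trial history
#' with a non-decreasing best-so-far trajectory. A failing objective
#' records the trial with metric 0 and a warning instead of aborting the
#' run. With `n_startup >= budget`, TPE is bit-identical to random search
#' under the same seed.
#'
#' @inheritParams random_search
#' @param method `"grid"`, `"random"` or `"tpe"`.
#' @param settings TPE settings (ignored otherwise).
#' @return an `optimization_report`: list with `best`, `trials`,
#'   `trajectory`, `method`, `seed`.
#' @export
optimize_params <- function(space, objective, method = c("tpe", "random",
                                                         "grid"),
                            budget = 60L, seed = 1L,
                            settings = tpe_settings()) {
  method <- match.arg(method)
  if (method == "grid") {
    res <- grid_search(space, objective)
  } else if (method == "random") {
    res <- random_search(space, objective, budget, seed)
  } else {
    stopifnot(budget >= 1L)
    trials <- with_seed(seed, {
      acc <- vector("list", budget)
      for (i in seq_len(budget)) {
        cfg <- if (i <= settings$n_startup) sample_config(space)
               else tpe_suggest(acc[seq_len(i - 1L)], space, settings)
        acc[[i]] <- run_objective(objective, cfg, i)
      }
      acc
    })
    metrics <- vapply(trials, `[[`, numeric(1), "metric")
    res <- list(best = trials[[which.max(metrics)]], trials = trials)
  }
  metrics <- vapply(res$trials, `[[`, numeric(1), "metric")
  structure(list(best = res$best, trials = res$trials,
                 trajectory = cummax(metrics), method = method,
                 seed = seed),
            class = "optimization_report")
}

#' @export
print.optimization_report <- function(x, ...) {
  cat(sprintf("<optimization_report: %s, %d trials, best metric %.4f>\n",
              x$method, length(x$trials), x$best$metric))
  invisible(x)
}

#' Serialize an optimization report as JSON lines (one trial per line)
#' @param report an `optimization_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials_jsonl <- function(report, path) {
  lines <- vapply(report$trials, function(t) {
    jsonlite::toJSON(list(trial_index = t$trial_index, metric = t$metric,
                          config = t$config), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- JSON space I/O --------------------------------------------------------

#' Read a parameter space from JSON
#'
#' Format: object mapping dimension name to either
#' `{"type":"cat","values":[...]}` or
#' `{"type":"int"|"float","low":a,"high":b}`.
#'
#' @param path JSON file path.
#' @return a [param_space()].
#' @export
read_param_space <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  dims <- lapply(raw, function(d) {
    switch(d$type,
      cat = dim_cat(unlist(d$values)),
      int = dim_int(d$low, d$high),
      float = dim_float(d$low, d$high),
      stop_crf("unknown dimension type '%s'", d$type,
               class = "crfvoter_config"))
  })
  do.call(param_space, dims)
}

# ---- canonical spaces ------------------------------------------------------

#' The CRF penalty/cost space used for exhaustive grid runs
#'
#' Ten cost values crossed with the two penalty kinds (20 cells), the
#' classic small space over which a full grid is feasible.
#' @return a [param_space()].
#' @export
crfpp_space <- function() {
  param_space(
    c = dim_cat(c(0.6, 1, 1.6, 3, 5, 7, 15, 50, 100, 1000)),
    a = dim_cat(c("CRF-L1", "CRF-L2"))
  )
}

#' Feature-template switch space for a CRF base learner
#'
#' Boolean feature switches plus the window/n-gram knobs, mirroring the
#' tunable surface of a classic CRF named-entity recognizer. Too large
#' for grid search; intended for random/TPE optimization.
#' @return a [param_space()].
#' @export
stanford_space <- function() {
  bools <- setdiff(.fc_switches, c("use_gaz_features", "sloppy_gazette"))
  dims <- c(
    setNames(lapply(bools, function(nm) dim_cat(c(TRUE, FALSE))), bools),
    list(max_left = dim_int(1L, 6L), max_right = dim_int(1L, 6L),
         max_ngram_leng = dim_int(1L, 6L),
         word_shape = dim_cat(c("chris2uselc", "plain")))
  )
  do.call(param_space, dims)
}
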