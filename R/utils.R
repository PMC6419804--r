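#' @keywords internal
"_PACKAGE"

#' @useDynLib crfvoter, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim runif rnorm rpois sd dnorm qchisq pbinom setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so that a single integer seed fixes a run.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one master seed into per-stage seeds, kept
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483587)
}

stop_crf <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "crfvoter_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Report-style rounding (0.675 -> 0.68 at 2 digits), matching the
#' two-decimal presentation used in the package's metric tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
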