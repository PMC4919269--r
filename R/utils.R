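# internal helpers shared across modules

.metkin_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a private RNG stream
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' package functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-subject substream seed from a global seed
#'
#' Stable string hash of the subject id combined with the global seed, so
#' adding or removing one subject never perturbs the draws of another.
#' Result is always a positive integer below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param id character identifier.
#' @return integer seed.
#' @export
substream_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(id) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) + h) %% 2147483629 + 1)
}

# (1 - exp(-x)) / x with the x -> 0 limit handled
.e1m <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 - x / 2 + x * x / 6, -expm1(-x) / x)
  out
}

# \int_0^S exp(-rate * s) ds, stable for rate -> 0
.int_exp <- function(rate, S) S * .e1m(rate * S)

# G(S) = \int_0^S (exp(-lambda s) - exp(-k2 s)) / (k2 - lambda) ds,
# the running integral of the unit impulse response convolution kernel.
# Stable for k2 ~ lambda (including both zero); elementwise vectorized.
.conv_int <- function(lambda, k2, S) {
  n <- max(length(lambda), length(k2), length(S))
  lambda <- rep_len(lambda, n); k2 <- rep_len(k2, n); S <- rep_len(S, n)
  near <- abs(k2 - lambda) <= 1e-7 * pmax(1, abs(k2), abs(lambda))
  out <- numeric(n)
  if (any(!near)) {
    i <- !near
    out[i] <- (.int_exp(lambda[i], S[i]) - .int_exp(k2[i], S[i])) /
      (k2[i] - lambda[i])
  }
  if (any(near)) {
    i <- near
    k <- (lambda[i] + k2[i]) / 2
    x <- k * S[i]
    out[i] <- ifelse(abs(x) < 1e-6,
                     S[i]^2 / 2 * (1 - 2 * x / 3 + x^2 / 4),
                     (1 - (1 + x) * exp(-x)) / (k * k))
  }
  out
}

.assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}
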