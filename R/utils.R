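# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators never perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically split one global seed into n child seeds (all < 2^31).
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# round() uses banker's rounding; quantile indexing here needs
# round-half-away-from-zero.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# First index (within [start_i, end_i]) starting a run of at least min_len
# consecutive TRUEs in cond[start_i:end_i]; NA if none.
first_sustained_run <- function(cond, start_i, min_len, end_i = length(cond)) {
  if (start_i > end_i) return(NA_integer_)
  r <- rle(cond[start_i:end_i])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (length(ok) == 0L) return(NA_integer_)
  as.integer(start_i + starts[ok[1L]] - 1L)
}

# Centered moving average with partial (renormalized) windows at the edges.
# Width k must be odd. Implemented with cumulative sums for exactness.
moving_average <- function(x, k) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  n <- length(x)
  if (k > n) stop("smoothing window longer than the signal")
  h <- (k - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Tiny rolling hash over the serialized object, for provenance stamping only
# (not cryptographic). Returns a hex string.
provenance_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  # drop the serialization header (R version bytes) so the hash is stable
  bytes <- bytes[-seq_len(14L)]
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

stop_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
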