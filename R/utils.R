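# Internal numerical and RNG helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal quadrature on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

# Derive a reproducible substream seed from a root seed. Each stochastic
# operation uses a fixed offset so that pipelines are bit-for-bit
# reproducible while operations stay statistically independent.
substream_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 2147483647L + 7919L * as.integer(offset)) %% 2147483647L
}

# Evaluate `expr` under a derived substream seed; a NULL seed leaves the
# caller's RNG state alone.
with_substream <- function(seed, offset, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(substream_seed(seed, offset), expr)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  invisible(x)
}

# time-window helper: [w[1], w[2]) selection on sample times
in_window <- function(t, window) {
  if (length(window) != 2L || !is.numeric(window) || window[2] <= window[1]) {
    stop("a time window must be a numeric pair c(start, end) with end > start",
         call. = FALSE)
  }
  t >= window[1] & t < window[2]
}

windows_disjoint <- function(w1, w2) {
  max(w1[1], w2[1]) >= min(w1[2], w2[2])
}
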