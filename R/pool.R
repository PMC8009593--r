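#' Reconstituted aequorin pool
#'
#' Describes a pool of coelenterazine-reconstituted aequorin molecules whose
#' photons can reach the sensor. `n_total` is expressed directly in expected
#' detectable photoelectrons: the geometric collection efficiency and the
#' photon detection efficiency of the sensor are constant multipliers and are
#' folded into the pool size rather than modelled separately.
#'
#' The calcium dependence of the consumption rate is a Hill law with
#' coefficient 3 by default, reflecting the three calcium ions that must bind
#' before the photoprotein oxidizes its substrate and emits.
#'
#' @param n_total expected number of detectable photoelectrons in the pool
#'   (dimensionless, >= 0).
#' @param lambda_max maximal fractional consumption rate at saturating
#'   calcium (1/s, > 0).
#' @param k_half calcium concentration of half-maximal consumption rate
#'   (molar, > 0).
#' @param hill_n Hill coefficient (>= 1).
#' @return An object of class `aequorin_pool`.
#' @examples
#' pool <- aequorin_pool(2e7)
#' consumption_rate(5e-6, pool)  # half-maximal at k_half
#' @export
aequorin_pool <- function(n_total, lambda_max = 1, k_half = 5e-6, hill_n = 3) {
  stop_if_not_scalar_number(n_total, "n_total", lower = 0)
  stop_if_not_scalar_number(lambda_max, "lambda_max", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(k_half, "k_half", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(hill_n, "hill_n", lower = 1)
  structure(
    list(n_total = n_total, lambda_max = lambda_max, k_half = k_half,
         hill_n = hill_n),
    class = "aequorin_pool"
  )
}

#' @export
print.aequorin_pool <- function(x, ...) {
  cat(sprintf(
    "<aequorin_pool> n_total = %.4g pe, lambda_max = %.3g /s, k_half = %.3g M, hill_n = %g\n",
    x$n_total, x$lambda_max, x$k_half, x$hill_n))
  invisible(x)
}

#' Calcium-dependent aequorin consumption rate
#'
#' Hill-form closure of the tri-calcium binding stoichiometry:
#' `lambda(ca) = lambda_max * ca^n / (ca^n + k_half^n)`.
#' Monotone non-decreasing in `ca` and bounded by `lambda_max`.
#'
#' @param ca calcium concentration(s), molar, >= 0. Vectorized.
#' @param pool an [aequorin_pool()].
#' @return Fractional consumption rate(s) in 1/s.
#' @export
consumption_rate <- function(ca, pool) {
  stopifnot(inherits(pool, "aequorin_pool"))
  if (!is.numeric(ca) || any(is.na(ca))) {
    stop("'ca' must be numeric and non-missing", call. = FALSE)
  }
  if (any(ca < 0)) stop("negative calcium concentration rejected", call. = FALSE)
  # written as 1/(1 + (k/ca)^n) so ca = 0 and ca = Inf are exact
  pool$lambda_max / (1 + (pool$k_half / ca)^pool$hill_n)
}

# inverse of the Hill law: calcium level giving a target fractional rate
ca_for_rate <- function(rate, pool) {
  x <- rate / pool$lambda_max
  if (any(x <= 0 | x >= 1)) stop("target rate must be in (0, lambda_max)")
  pool$k_half * (x / (1 - x))^(1 / pool$hill_n)
}

#' Geometric dilution series of an aequorin pool
#'
#' Returns `n_points` pools with `n_total` scaled by
#' `ratio^0, ratio^-1, ..., ratio^-(n_points - 1)`, i.e. the 2-fold serial
#' dilution protocol used for response-linearity characterization (12 points
#' of a ratio-2 progression span `log10(2^11) ~ 3.31` decades).
#'
#' @param pool the undiluted [aequorin_pool()].
#' @param ratio dilution ratio (> 1).
#' @param n_points number of points in the series (>= 2).
#' @return A list of `aequorin_pool` objects with attribute `factors`
#'   holding the concentration factors.
#' @export
dilution_series <- function(pool, ratio = 2, n_points = 12) {
  stopifnot(inherits(pool, "aequorin_pool"))
  stop_if_not_scalar_number(ratio, "ratio", lower = 1, strict = TRUE)
  stop_if_not_scalar_number(n_points, "n_points", lower = 2)
  factors <- ratio^(-(0:(n_points - 1)))
  pools <- lapply(factors, function(f) {
    p <- pool
    p$n_total <- pool$n_total * f
    p
  })
  attr(pools, "factors") <- factors
  pools
}
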