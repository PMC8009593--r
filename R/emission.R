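#' Expected photon-rate profile from an aequorin pool and calcium scenario
#'
#' Integrates the consumption dynamics `dN/dt = -lambda(Ca(t)) N(t)` on the
#' scenario grid with an exact per-step exponential update
#' `N[k+1] = N[k] exp(-lambda[k] dt)` (unconditionally stable, positivity
#' preserving, and exact whenever calcium is constant over a step). The
#' expected photoelectron rate at the sensor is `L(t) = lambda(Ca(t)) N(t)`,
#' so the emitted light integrates to the number of molecules consumed:
#' `integral(L) = N(0) - N(end)` up to quadrature error.
#'
#' The grid must resolve the kinetics: if `lambda * dt > 0.1` anywhere the
#' integration error is no longer negligible and the call is refused.
#'
#' @param pool an [aequorin_pool()].
#' @param scenario a [ca_scenario()].
#' @return An object of class `emission_profile` with fields `t` (s), `rate`
#'   (expected photoelectron rate, Hz), `n_remaining` (pool trajectory),
#'   `n_total`, and `provenance`.
#' @examples
#' pool <- aequorin_pool(1e5, lambda_max = 1)
#' sc <- ca_scenario(list(seg_constant(0, 1e-2)), duration = 10, dt = 0.01)
#' prof <- emit(pool, sc)
#' max(prof$rate)  # ~ lambda_max * n_total
#' @export
emit <- function(pool, scenario) {
  stopifnot(inherits(pool, "aequorin_pool"), inherits(scenario, "ca_scenario"))
  tr <- ca_trace(scenario)
  t <- tr$t
  n <- length(t)
  dt <- scenario$dt
  lam_node <- consumption_rate(tr$ca, pool)
  # left-node rate per step: exact for piecewise-constant calcium, so a step
  # at a grid node takes effect exactly at that node rather than bleeding
  # into the preceding bin
  lam_step <- lam_node[-n]
  worst <- max(lam_step) * dt
  if (worst > 0.1) {
    stop(sprintf(
      "time step too coarse for the consumption kinetics: max(lambda*dt) = %.3g > 0.1; reduce dt below %.3g s",
      worst, 0.1 / max(lam_step)), call. = FALSE)
  }
  N <- pool$n_total * exp(-c(0, cumsum(lam_step * dt)))
  structure(
    list(t = t, rate = lam_node * N, n_remaining = N, n_total = pool$n_total,
         provenance = scenario$provenance),
    class = "emission_profile"
  )
}

#' Constant-rate emission profile
#'
#' Convenience constructor for a constant expected rate (e.g. a dark-only
#' recording uses `rate = 0` and lets the detector configuration supply the
#' dark counts). The bookkeeping pool trajectory decreases linearly so that
#' the conservation invariant `integral(L) = N(0) - N(end)` holds.
#'
#' @param rate expected photoelectron rate (Hz, >= 0).
#' @param duration duration (s).
#' @param dt grid step (s).
#' @param provenance free-text note.
#' @export
emission_constant <- function(rate, duration, dt = 0.01,
                              provenance = "constant rate") {
  stop_if_not_scalar_number(rate, "rate", lower = 0)
  stop_if_not_scalar_number(duration, "duration", lower = 0, strict = TRUE)
  n <- round(duration / dt)
  t <- (0:n) * dt
  structure(
    list(t = t, rate = rep(rate, n + 1L), n_remaining = rate * duration - rate * t,
         n_total = rate * duration, provenance = provenance),
    class = "emission_profile"
  )
}

#' @export
print.emission_profile <- function(x, ...) {
  cat(sprintf(
    "<emission_profile> %.4g s on %d nodes; peak %.4g Hz; pool %.4g -> %.4g pe\n",
    max(x$t), length(x$t), max(x$rate), x$n_remaining[1],
    x$n_remaining[length(x$n_remaining)]))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

# linear interpolation of the expected rate at arbitrary times
profile_rate_at <- function(profile, times) {
  stats::approx(profile$t, profile$rate, xout = times, rule = 2)$y
}

#' Write / read an emission profile as a delimited text table
#'
#' Two tab-separated columns (`time_s`, `rate_hz`) preceded by commented
#' header lines carrying the provenance and the initial pool size, so that
#' the pool trajectory can be reconstructed on read by integrating the rate.
#'
#' @param profile an `emission_profile`.
#' @param path file path.
#' @return `write_emission_profile()` returns `path` invisibly;
#'   `read_emission_profile()` returns an `emission_profile`.
#' @export
write_emission_profile <- function(profile, path) {
  stopifnot(inherits(profile, "emission_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# aequosim emission profile",
    paste0("# provenance: ", profile$provenance),
    sprintf("# n_total: %.15g", profile$n_total),
    "time_s\trate_hz"), con)
  utils::write.table(
    data.frame(time_s = profile$t, rate_hz = profile$rate),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emission_profile
#' @export
read_emission_profile <- function(path) {
  header <- readLines(path, n = 10L)
  prov <- sub("^# provenance: ", "", grep("^# provenance: ", header, value = TRUE))
  n_total <- as.numeric(sub("^# n_total: ", "",
                            grep("^# n_total: ", header, value = TRUE)))
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  consumed <- cumtrapz(d$time_s, d$rate_hz)
  structure(
    list(t = d$time_s, rate = d$rate_hz, n_remaining = n_total - consumed,
         n_total = n_total, provenance = if (length(prov)) prov else ""),
    class = "emission_profile"
  )
}
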