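#' Sample photon and dark-count arrivals from an emission profile
#'
#' Superposes an inhomogeneous Poisson process with intensity `L(t)` (the
#' expected photoelectron rate of the profile) and a homogeneous dark-count
#' process at `config$dcr`. In the event regime, signal arrivals are drawn by
#' thinning against the per-interval maximum of the piecewise-linear rate;
#' in the binned hybrid regime (peak rate above `config$hybrid_threshold`,
#' or expected arrivals above `config$hybrid_max_events`) per-bin Poisson
#' counts are drawn on the profile grid instead. The two regimes agree in
#' distribution at the counting-window level.
#'
#' @param profile an `emission_profile`.
#' @param config a [detector_config()].
#' @return An object of class `arrival_stream`, either mode `"event_list"`
#'   (strictly increasing arrival times) or `"binned"` (per-bin counts with
#'   their generating rates).
#' @export
sample_arrivals <- function(profile, config = detector_config()) {
  stopifnot(inherits(profile, "emission_profile"),
            inherits(config, "detector_config"))
  t <- profile$t
  n <- length(t)
  L <- pmax(profile$rate, 0)
  if (any(!is.finite(L))) stop("profile rate must be finite", call. = FALSE)
  dtv <- diff(t)
  span <- c(t[1L], t[n])
  expected <- trapz(t, L) + config$dcr * (span[2] - span[1])
  binned <- (max(L) + config$dcr) > config$hybrid_threshold ||
    expected > config$hybrid_max_events
  if (binned) {
    rbar <- (L[-1L] + L[-n]) / 2 + config$dcr
    counts <- with_substream(config$seed, 1L,
                             stats::rpois(n - 1L, rbar * dtv))
    structure(
      list(mode = "binned", t_mid = t[-n] + dtv / 2, bin_dt = dtv,
           rate = rbar, counts = counts, counted = FALSE,
           seed = config$seed, span = span),
      class = "arrival_stream"
    )
  } else {
    times <- with_substream(config$seed, 1L, {
      M <- pmax(L[-1L], L[-n]) + config$dcr
      nk <- stats::rpois(n - 1L, M * dtv)
      tot <- sum(nk)
      if (tot == 0L) {
        numeric(0)
      } else {
        idx <- rep.int(seq_len(n - 1L), nk)
        u <- stats::runif(tot)
        # linear interpolation of the signal rate at the candidate times
        rate_at <- L[idx] + (L[idx + 1L] - L[idx]) * u + config$dcr
        keep <- stats::runif(tot) < rate_at / M[idx]
        # ties at the RNG resolution are one physical pulse
        unique(sort(t[idx][keep] + u[keep] * dtv[idx][keep]))
      }
    })
    structure(
      list(mode = "event_list", times = times, counted = FALSE,
           seed = config$seed, span = span),
      class = "arrival_stream"
    )
  }
}

#' @export
print.arrival_stream <- function(x, ...) {
  if (x$mode == "event_list") {
    cat(sprintf("<arrival_stream:event_list> %d events on [%.4g, %.4g] s%s\n",
                length(x$times), x$span[1], x$span[2],
                if (x$counted) " (dead time applied)" else ""))
  } else {
    cat(sprintf("<arrival_stream:binned> %d bins, %d events on [%.4g, %.4g] s%s\n",
                length(x$counts), sum(x$counts), x$span[1], x$span[2],
                if (x$counted) " (dead time applied)" else ""))
  }
  invisible(x)
}

#' Apply discriminator dead time to an arrival stream
#'
#' Event mode: under the paralyzable model an arrival is counted only if no
#' arrival (counted or not) occurred within the preceding `pulse_tau`; under
#' the non-paralyzable model only counted events extend the dead interval.
#' The output times are a subset of the input times.
#'
#' Binned mode: each bin's arrival count is thinned binomially with the
#' closed-form survival fraction `expected_counted_rate(rate) / rate`, which
#' leaves the per-bin counted counts exactly Poisson with the counted rate as
#' mean (a Poisson count thinned binomially is Poisson).
#'
#' @param stream an `arrival_stream`.
#' @param config a [detector_config()].
#' @return The stream with dead-time losses applied (`counted = TRUE`).
#' @export
apply_deadtime <- function(stream, config = detector_config()) {
  stopifnot(inherits(stream, "arrival_stream"),
            inherits(config, "detector_config"))
  tau <- config$pulse_tau
  if (stream$mode == "event_list") {
    times <- stream$times
    if (is.unsorted(times)) stop("unsorted arrival times rejected", call. = FALSE)
    keep <- if (length(times) == 0L || tau <= 0) {
      rep(TRUE, length(times))
    } else if (config$deadtime_model == "paralyzable") {
      c(TRUE, diff(times) > tau)
    } else {
      nonparalyzable_keep(times, tau)
    }
    stream$times <- times[keep]
  } else {
    f <- ifelse(stream$rate > 0,
                expected_counted_rate(stream$rate, config) / stream$rate, 1)
    stream$counts <- with_substream(stream$seed, 2L,
                                    stats::rbinom(length(stream$counts),
                                                  stream$counts, f))
  }
  stream$counted <- TRUE
  stream
}

#' Closed-form counted rate under dead time
#'
#' For a homogeneous true arrival rate `n` and dead time `tau`:
#' paralyzable `n * exp(-n * tau)` (maximal at `n = 1/tau`), non-paralyzable
#' `n / (1 + n * tau)`. Serves as the analytic oracle for the event-level
#' simulation and as the loss law of the binned hybrid regime.
#'
#' @param true_rate true arrival rate(s), Hz. Vectorized.
#' @param config a [detector_config()] supplying `pulse_tau` and the model.
#' @return Counted rate(s), Hz.
#' @export
expected_counted_rate <- function(true_rate, config = detector_config()) {
  if (any(true_rate < 0)) stop("'true_rate' must be >= 0", call. = FALSE)
  tau <- config$pulse_tau
  if (config$deadtime_model == "paralyzable") {
    true_rate * exp(-true_rate * tau)
  } else {
    true_rate / (1 + true_rate * tau)
  }
}

#' Pile-up probability at a given arrival rate
#'
#' Probability that at least one further arrival falls within one pulse
#' duration of a given arrival: `1 - exp(-true_rate * pulse_tau)`. At 2 MHz
#' with a 30 ns pulse this is 5.8%, the few-percent pile-up regime quoted for
#' megahertz counting.
#'
#' @inheritParams expected_counted_rate
#' @return Probability in `[0, 1)`. Vectorized.
#' @export
pileup_probability <- function(true_rate, config = detector_config()) {
  if (any(true_rate < 0)) stop("'true_rate' must be >= 0", call. = FALSE)
  1 - exp(-true_rate * config$pulse_tau)
}

#' Count arrivals in consecutive scaler windows
#'
#' Histograms counted events into consecutive windows of length `window`
#' starting at the stream's span start (a trailing partial window is
#' dropped) and reports each window as a frequency `counts / window`.
#' Counts clip at the scaler depth `2^scaler_bits - 1`, flagged per window.
#'
#' @param stream an `arrival_stream` (binned-mode bins must tile the
#'   windows exactly).
#' @param window window length (s), default 100 ms.
#' @param scaler_bits scaler counter depth.
#' @return A `count_trace`: data frame with columns `t` (window start, s),
#'   `counts`, `freq` (Hz) and `saturated`, plus attributes `window` and
#'   `baseline_subtracted`.
#' @export
count_windows <- function(stream, window = 0.1, scaler_bits = 32) {
  stopifnot(inherits(stream, "arrival_stream"))
  stop_if_not_scalar_number(window, "window", lower = 0, strict = TRUE)
  span <- stream$span
  n_win <- floor((span[2] - span[1]) / window + 1e-9)
  if (n_win < 1L) stop("stream shorter than one window", call. = FALSE)
  if (stream$mode == "event_list") {
    idx <- floor((stream$times - span[1]) / window) + 1
    idx <- idx[idx >= 1 & idx <= n_win]
    counts <- tabulate(idx, nbins = n_win)
  } else {
    bpw <- window / stats::median(stream$bin_dt)
    if (abs(bpw - round(bpw)) > 1e-6) {
      stop("'window' must be an integer multiple of the simulation bin width",
           call. = FALSE)
    }
    bpw <- as.integer(round(bpw))
    m <- n_win * bpw
    counts <- colSums(matrix(stream$counts[seq_len(m)], nrow = bpw))
  }
  cap <- 2^scaler_bits - 1
  saturated <- counts > cap
  counts <- pmin(counts, cap)
  out <- data.frame(
    t = span[1] + (seq_len(n_win) - 1) * window,
    counts = counts,
    freq = counts / window,
    saturated = saturated
  )
  class(out) <- c("count_trace", "data.frame")
  attr(out, "window") <- window
  attr(out, "baseline_subtracted") <- FALSE
  out
}

#' Simulate the full single-photon-counting branch
#'
#' Arrival sampling, dead time, and windowed counting in one call.
#'
#' @param profile an `emission_profile`.
#' @param config a [detector_config()].
#' @param window scaler window (s).
#' @return A `count_trace`.
#' @export
spc_simulate <- function(profile, config = detector_config(), window = 0.1) {
  stream <- sample_arrivals(profile, config)
  stream <- apply_deadtime(stream, config)
  count_windows(stream, window = window, scaler_bits = config$scaler_bits)
}

#' Write / read a count trace as a delimited text table
#'
#' Tab-separated columns `t_s`, `counts`, `freq_hz`, `saturated` with a
#' commented header carrying the window length — the on-disk twin of the
#' scaler output.
#'
#' @param trace a `count_trace`.
#' @param path file path.
#' @export
write_count_trace <- function(trace, path) {
  stopifnot(inherits(trace, "count_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# aequosim count trace",
               sprintf("# window_s: %.15g", attr(trace, "window")),
               "t_s\tcounts\tfreq_hz\tsaturated"), con)
  utils::write.table(
    data.frame(trace$t, trace$counts, trace$freq, as.integer(trace$saturated)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_trace
#' @export
read_count_trace <- function(path) {
  header <- readLines(path, n = 5L)
  window <- as.numeric(sub("^# window_s: ", "",
                           grep("^# window_s: ", header, value = TRUE)))
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- data.frame(t = d$t_s, counts = d$counts, freq = d$freq_hz,
                    saturated = as.logical(d$saturated))
  class(out) <- c("count_trace", "data.frame")
  attr(out, "window") <- window
  attr(out, "baseline_subtracted") <- FALSE
  out
}
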