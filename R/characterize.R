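#' Subtract the pre-stimulation baseline from a trace
#'
#' Subtracts the mean of the samples inside `baseline_window` (which must
#' precede stimulation and contain at least 10 samples) from the whole
#' trace. For a count trace the subtraction acts on the frequency values
#' (counts are updated to keep `freq = counts / window` exact); for a charge
#' trace it acts on the photoelectron-equivalent and charge values, leaving
#' the raw ADC record untouched. The subtracted level is stored in the
#' `baseline_value` attribute.
#'
#' @param trace a `count_trace` or `charge_trace`.
#' @param baseline_window numeric pair `c(start, end)` in seconds. The
#'   default covers the 30 s of quiet acquisition that precede injection in
#'   the standard protocol.
#' @return The baseline-subtracted trace (`baseline_subtracted = TRUE`).
#' @export
baseline_subtract <- function(trace, baseline_window = c(0, 30)) {
  UseMethod("baseline_subtract")
}

baseline_idx <- function(trace, baseline_window) {
  sel <- which(in_window(trace$t, baseline_window))
  if (length(sel) == 0L) stop("empty baseline window", call. = FALSE)
  if (length(sel) < 10L) {
    stop("baseline window must contain at least 10 samples", call. = FALSE)
  }
  sel
}

#' @export
baseline_subtract.count_trace <- function(trace, baseline_window = c(0, 30)) {
  sel <- baseline_idx(trace, baseline_window)
  b <- mean(trace$freq[sel])
  trace$freq <- trace$freq - b
  trace$counts <- trace$freq * attr(trace, "window")
  attr(trace, "baseline_value") <- b
  attr(trace, "baseline_subtracted") <- TRUE
  trace
}

#' @export
baseline_subtract.charge_trace <- function(trace, baseline_window = c(0, 30)) {
  sel <- baseline_idx(trace, baseline_window)
  b <- mean(trace$pe_equiv[sel])
  trace$pe_equiv <- trace$pe_equiv - b
  trace$charge <- trace$charge - b * attr(trace, "charge_per_pe")
  attr(trace, "baseline_value") <- b
  attr(trace, "baseline_subtracted") <- TRUE
  trace
}

#' Integrated luminescence intensity over a signal window
#'
#' Sums a baseline-subtracted trace over `signal_window` and expresses the
#' result in photoelectrons in both branches, so SPC and CI integrals are
#' directly comparable. For counting, this is the sum of per-window counts.
#' For charge integration, each gate samples only a `gate * sampling_rate`
#' duty fraction of the light, so the per-sample photoelectron equivalents
#' are scaled by `sample_dt / gate` — the integral then estimates the total
#' number of photoelectrons that arrived during the window, i.e. the number
#' of aequorin molecules consumed.
#'
#' @param trace a baseline-subtracted `count_trace` or `charge_trace`.
#' @param signal_window numeric pair `c(start, end)`, seconds; must overlap
#'   the trace.
#' @return Total photoelectrons (numeric scalar).
#' @export
integrated_intensity <- function(trace, signal_window) {
  UseMethod("integrated_intensity")
}

check_signal_window <- function(trace, signal_window) {
  if (!isTRUE(attr(trace, "baseline_subtracted"))) {
    stop("trace must be baseline-subtracted first (see baseline_subtract())",
         call. = FALSE)
  }
  sel <- which(in_window(trace$t, signal_window))
  if (length(sel) == 0L) stop("signal window outside trace", call. = FALSE)
  sel
}

#' @export
integrated_intensity.count_trace <- function(trace, signal_window) {
  sel <- check_signal_window(trace, signal_window)
  sum(trace$freq[sel]) * attr(trace, "window")
}

#' @export
integrated_intensity.charge_trace <- function(trace, signal_window) {
  sel <- check_signal_window(trace, signal_window)
  sum(trace$pe_equiv[sel]) * attr(trace, "sample_dt") / attr(trace, "gate")
}

#' Peak frequency of a trace
#'
#' Maximum of the baseline-subtracted trace after a centered moving-average
#' smoother (default width 3 samples) that suppresses single-window shot
#' noise without distorting minute-scale kinetics. Charge traces are
#' converted to rate units (`pe_equiv / gate`).
#'
#' @param trace a baseline-subtracted `count_trace` or `charge_trace`.
#' @param smooth_width moving-average width in samples (odd; 1 disables).
#' @return A list with `peak_hz` and `t_peak` (s).
#' @export
peak_frequency <- function(trace, smooth_width = 3) {
  stopifnot(inherits(trace, "count_trace") || inherits(trace, "charge_trace"))
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  vals <- if (inherits(trace, "count_trace")) {
    trace$freq
  } else {
    trace$pe_equiv / attr(trace, "gate")
  }
  if (smooth_width > 1) {
    sm <- stats::filter(vals, rep(1 / smooth_width, smooth_width), sides = 2)
    vals <- as.numeric(sm)
  }
  i <- which.max(vals)
  list(peak_hz = vals[i], t_peak = trace$t[i])
}

#' Log-log linearity fit of integrated intensity versus concentration
#'
#' Ordinary least squares of `log2(integral)` on `log2(concentration
#' factor)` over the non-excluded points. In this base, a power law
#' `y = m x^a` maps to a straight line with slope `a` and intercept
#' `q = log2(m)`, and intercept differences between two acquisition branches
#' convert directly into a sensitivity ratio `2^(q_a - q_b)` (see
#' [sensitivity_ratio()]); base 2 matches a 2-fold dilution design, where
#' the concentration factors sit at integer abscissae.
#'
#' @param conc concentration factors (e.g. `2^-(0:11)`).
#' @param integrals integrated intensities (photoelectrons); every included
#'   value must be positive.
#' @param exclude indices to exclude, or one of the presets `"lowest-3"` /
#'   `"highest-3"` (by concentration) matching the standard trimmed fits.
#' @return A `linearity_fit` with `slope`, `slope_se`, `intercept`,
#'   `intercept_se` (log2 units), `excluded`, `n_used`, `residuals`,
#'   `log_base`.
#' @export
fit_loglog <- function(conc, integrals, exclude = NULL) {
  if (length(conc) != length(integrals)) {
    stop("'conc' and 'integrals' must have the same length", call. = FALSE)
  }
  if (is.character(exclude)) {
    exclude <- switch(
      exclude,
      "lowest-3" = order(conc)[1:3],
      "highest-3" = order(conc, decreasing = TRUE)[1:3],
      stop("unknown exclusion preset: ", exclude, call. = FALSE)
    )
  }
  exclude <- sort(unique(as.integer(exclude)))
  included <- setdiff(seq_along(conc), exclude)
  if (length(included) < 3L) {
    stop("fewer than 3 points left after exclusion", call. = FALSE)
  }
  if (any(integrals[included] <= 0)) {
    stop("non-positive integral among included points; exclude it or treat it as censored",
         call. = FALSE)
  }
  x <- log2(conc[included])
  y <- log2(integrals[included])
  fit <- stats::lm(y ~ x)
  s <- summary(fit)$coefficients
  structure(
    list(slope = unname(s["x", "Estimate"]),
         slope_se = unname(s["x", "Std. Error"]),
         intercept = unname(s["(Intercept)", "Estimate"]),
         intercept_se = unname(s["(Intercept)", "Std. Error"]),
         excluded = exclude, n_used = length(included),
         residuals = unname(stats::residuals(fit)), log_base = 2),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf(
    "<linearity_fit> slope a = %.4f +- %.4f, intercept q = %.3f +- %.3f (log2), n = %d%s\n",
    x$slope, x$slope_se, x$intercept, x$intercept_se, x$n_used,
    if (length(x$excluded)) paste0(", excluded: ",
                                   paste(x$excluded, collapse = ",")) else ""))
  invisible(x)
}

#' Sensitivity ratio from two log2 intercepts
#'
#' `2^(q_a - q_b)`: the ratio of the sensitivities of two acquisition
#' branches whose log2-log2 response fits have intercepts `q_a` and `q_b`.
#'
#' @param q_a,q_b intercepts in log2 units.
#' @return The ratio (numeric scalar).
#' @export
sensitivity_ratio <- function(q_a, q_b) 2^(q_a - q_b)

#' Analytic limit of detection from dark-count statistics
#'
#' With the noise due solely to a Poisson dark-count rate `dcr`, the rate
#' estimated over a sampling interval `dt` fluctuates with standard
#' deviation `sqrt(dcr / dt)`; the limit of detection at `k` sigma is
#' `LoD = k * sqrt(dcr / dt)`. At 904 kHz this gives 9.0 kHz for the 100 ms
#' counting window and 1.28 MHz for a 5 us integration gate.
#'
#' @param dcr dark-count rate (Hz, >= 0).
#' @param dt sampling interval: counting window or integration gate (s).
#' @param criterion_sigma detection criterion in dark sigmas (default 3).
#' @return A `lod_result`.
#' @export
lod_analytic <- function(dcr, dt, criterion_sigma = 3) {
  stop_if_not_scalar_number(dcr, "dcr", lower = 0)
  stop_if_not_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  structure(
    list(mode = "analytic", lod = criterion_sigma * sqrt(dcr / dt),
         dcr = dcr, dt = dt, criterion_sigma = criterion_sigma),
    class = "lod_result"
  )
}

#' Empirical limit of detection from a dark trace
#'
#' Computes the dark mean and standard deviation of a stationary dark
#' recording and converts the `mu + k sigma` detection criterion into rate
#' units using the channel's linear response: counting windows read rate
#' directly, so `LoD = k * sigma` in Hz; charge gates respond with
#' `rate * gate * charge_per_pe` coulombs per hertz, so
#' `LoD = k * sigma_charge / (gate * charge_per_pe)`. Block-averaged charge
#' traces use the same conversion on the averaged sigma, which is how
#' averaging buys sensitivity.
#'
#' @param trace a dark `count_trace` or `charge_trace` (>= 100 samples, no
#'   stimulus).
#' @param criterion_sigma detection criterion in dark sigmas (default 3).
#' @return A `lod_result` with fields `mu` and `sigma` in the channel's
#'   native units.
#' @export
lod_empirical <- function(trace, criterion_sigma = 3) {
  stopifnot(inherits(trace, "count_trace") || inherits(trace, "charge_trace"))
  if (nrow(trace) < 100L) {
    stop("need at least 100 dark samples for an empirical LoD", call. = FALSE)
  }
  if (inherits(trace, "count_trace")) {
    mu <- mean(trace$freq)
    sigma <- stats::sd(trace$freq)
    lod <- criterion_sigma * sigma
    mode <- "empirical_spc"
    dt <- attr(trace, "window")
  } else {
    mu <- mean(trace$charge)
    sigma <- stats::sd(trace$charge)
    lod <- criterion_sigma * sigma / (attr(trace, "gate") * attr(trace, "charge_per_pe"))
    mode <- "empirical_ci"
    dt <- attr(trace, "gate")
  }
  structure(
    list(mode = mode, lod = lod, mu = mu, sigma = sigma, dt = dt,
         block = attr(trace, "block") %||% 1L,
         criterion_sigma = criterion_sigma, n = nrow(trace)),
    class = "lod_result"
  )
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result:%s> LoD = %.4g Hz (criterion %g sigma)\n",
              x$mode, x$lod, x$criterion_sigma))
  invisible(x)
}

#' Agonist/lysis discharge ratio A/T
#'
#' Integrated intensities of the agonist (ATP) and lysis (Triton X-100)
#' responses after baseline subtraction, and their ratio `A/T`. Because one
#' aequorin molecule emits exactly one photon, `A/T` estimates the fraction
#' of the pool consumed by the agonist relative to the fraction discharged by
#' lysis — a figure of merit that is independent of the absolute pool size
#' unless channel nonlinearities (pile-up) distort one of the integrals.
#'
#' @param trace a baseline-subtracted `count_trace` or `charge_trace`.
#' @param atp_window,triton_window disjoint time windows `c(start, end)` in
#'   seconds, both inside the trace.
#' @return A `discharge_ratio` with fields `A`, `T`, `ratio` and the
#'   window definitions.
#' @export
discharge_ratio <- function(trace, atp_window, triton_window) {
  if (!windows_disjoint(atp_window, triton_window)) {
    stop("agonist and lysis windows must be disjoint", call. = FALSE)
  }
  A <- integrated_intensity(trace, atp_window)
  T_ <- integrated_intensity(trace, triton_window)
  if (T_ <= 0) stop("lysis integral T must be positive", call. = FALSE)
  structure(
    list(A = A, T = T_, ratio = A / T_, atp_window = atp_window,
         triton_window = triton_window),
    class = "discharge_ratio"
  )
}

#' @export
print.discharge_ratio <- function(x, ...) {
  cat(sprintf("<discharge_ratio> A = %.4g pe, T = %.4g pe, A/T = %.4g\n",
              x$A, x$T, x$ratio))
  invisible(x)
}
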