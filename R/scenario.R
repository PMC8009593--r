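#' Calcium scenario segments
#'
#' A calcium scenario is an ordered list of non-overlapping segments covering
#' `[0, duration]`. Each segment starts at `start` (seconds) and describes the
#' free-calcium trajectory until the next segment begins:
#'
#' * `seg_constant()` — constant level (resting baseline or a step).
#' * `seg_rise()` — exponential approach from `from` to `to` with time
#'   constant `tau`, e.g. injection of a calcium bolus mixing into the
#'   chamber.
#' * `seg_transient()` — rise--decay transient above `baseline` peaking at
#'   `peak`, with rise constant `tau_r` and decay constant `tau_d` (an
#'   agonist-evoked cytosolic transient).
#' * `seg_oscillation()` — a periodic train of rise--decay events above
#'   `baseline`, one event every `period` seconds, each peaking at `peak`.
#'
#' All concentrations are molar and must be non-negative.
#'
#' @param start segment start time (s).
#' @param ca,from,to,baseline,peak calcium levels (M).
#' @param tau,tau_r,tau_d time constants (s).
#' @param period oscillation period (s).
#' @return A segment descriptor used by [ca_scenario()].
#' @name ca_segments
NULL

new_segment <- function(start, type, params) {
  stop_if_not_scalar_number(start, "start", lower = 0)
  bad <- vapply(params, function(p) !is.numeric(p) || length(p) != 1L ||
                  !is.finite(p) || p < 0, logical(1))
  if (any(bad)) {
    stop("segment parameters must be single non-negative numbers: ",
         paste(names(params)[bad], collapse = ", "), call. = FALSE)
  }
  c(list(start = start, type = type), params)
}

#' @rdname ca_segments
#' @export
seg_constant <- function(start, ca) new_segment(start, "constant", list(ca = ca))

#' @rdname ca_segments
#' @export
seg_rise <- function(start, from, to, tau) {
  new_segment(start, "rise", list(from = from, to = to, tau = tau))
}

#' @rdname ca_segments
#' @export
seg_transient <- function(start, baseline, peak, tau_r = 5, tau_d = 20) {
  new_segment(start, "transient",
              list(baseline = baseline, peak = peak, tau_r = tau_r,
                   tau_d = tau_d))
}

#' @rdname ca_segments
#' @export
seg_oscillation <- function(start, baseline, peak, period = 20, tau_r = 1,
                            tau_d = 4) {
  new_segment(start, "oscillation",
              list(baseline = baseline, peak = peak, period = period,
                   tau_r = tau_r, tau_d = tau_d))
}

# normalized rise--decay shape, unit peak, zero for s < 0
transient_shape <- function(s, tau_r, tau_d) {
  v <- numeric(length(s))
  ok <- s >= 0
  sv <- s[ok]
  raw <- (1 - exp(-sv / tau_r)) * exp(-sv / tau_d)
  s_peak <- tau_r * log(1 + tau_d / tau_r)
  norm <- (1 - exp(-s_peak / tau_r)) * exp(-s_peak / tau_d)
  v[ok] <- raw / norm
  v
}

#' Assemble a calcium scenario
#'
#' @param segments list of segment descriptors (see [ca_segments]) with
#'   strictly increasing start times, the first at 0.
#' @param duration total duration (s).
#' @param dt time step of the scenario grid (s); must resolve the fastest
#'   consumption rate (see [emit()]).
#' @param provenance free-text note carried through to emission profiles.
#' @return An object of class `ca_scenario`.
#' @export
ca_scenario <- function(segments, duration, dt = 0.01, provenance = "") {
  stop_if_not_scalar_number(duration, "duration", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  if (!is.list(segments) || length(segments) == 0L) {
    stop("'segments' must be a non-empty list", call. = FALSE)
  }
  starts <- vapply(segments, `[[`, numeric(1), "start")
  if (starts[1] != 0) stop("the first segment must start at t = 0", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("segment start times must be strictly increasing", call. = FALSE)
  }
  if (any(starts >= duration)) {
    stop("all segments must start before 'duration'", call. = FALSE)
  }
  structure(
    list(segments = segments, duration = duration, dt = dt,
         provenance = provenance),
    class = "ca_scenario"
  )
}

#' @export
print.ca_scenario <- function(x, ...) {
  cat(sprintf("<ca_scenario> %d segment(s), duration %.4g s, dt %.3g s\n",
              length(x$segments), x$duration, x$dt))
  for (s in x$segments) {
    cat(sprintf("  t >= %-8.4g %s\n", s$start, s$type))
  }
  invisible(x)
}

# Evaluate the calcium trajectory on the scenario grid.
ca_trace <- function(scenario) {
  stopifnot(inherits(scenario, "ca_scenario"))
  n <- round(scenario$duration / scenario$dt)
  t <- (0:n) * scenario$dt
  ca <- numeric(n + 1L)
  segs <- scenario$segments
  starts <- vapply(segs, `[[`, numeric(1), "start")
  ends <- c(starts[-1L], Inf)
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    idx <- which(t >= starts[i] & t < ends[i])
    if (i == length(segs)) idx <- which(t >= starts[i])
    if (length(idx) == 0L) next
    s <- t[idx] - seg$start
    ca[idx] <- switch(
      seg$type,
      constant = rep(seg$ca, length(idx)),
      rise = seg$to + (seg$from - seg$to) * exp(-s / seg$tau),
      transient = seg$baseline +
        (seg$peak - seg$baseline) * transient_shape(s, seg$tau_r, seg$tau_d),
      oscillation = {
        v <- rep(seg$baseline, length(idx))
        seg_len <- max(s)
        events <- seq(0, seg_len, by = seg$period)
        for (e in events) {
          v <- v + (seg$peak - seg$baseline) *
            transient_shape(s - e, seg$tau_r, seg$tau_d)
        }
        v
      },
      stop("unknown segment type: ", seg$type)
    )
  }
  list(t = t, ca = ca)
}

#' Lysate discharge scenario: calcium bolus injected into the chamber
#'
#' Resting baseline followed by an exponential mixing rise of the calcium
#' level after injection of a calcium bolus, as in the dilution-series
#' characterization runs (30 s of baseline, then injection).
#'
#' @param ca_level equilibrated calcium level after mixing (M).
#' @param inject_time injection time (s).
#' @param mix_tau mixing time constant of the injected bolus (s).
#' @param duration,dt scenario grid.
#' @param resting_ca resting calcium level (M).
#' @export
scenario_lysate <- function(ca_level, inject_time = 30, mix_tau = 2,
                            duration = 50, dt = 0.01, resting_ca = 1e-7) {
  ca_scenario(
    list(seg_constant(0, resting_ca),
         seg_rise(inject_time, from = resting_ca, to = ca_level, tau = mix_tau)),
    duration = duration, dt = dt,
    provenance = sprintf("lysate discharge: inject to %.3g M at %g s", ca_level,
                         inject_time)
  )
}

# Bisection on a scalar calcium parameter so that an emitted-profile summary
# hits a target. `build` maps ca -> scenario; `stat` maps profile -> number.
solve_ca <- function(pool, build, stat, target, lo, hi, tol = 1e-3,
                     what = "target") {
  f <- function(ca) stat(emit(pool, build(ca))) - target
  flo <- f(lo); fhi <- f(hi)
  if (fhi < 0) {
    stop(sprintf("%s %.4g unreachable: maximum attainable is %.4g", what,
                 target, fhi + target), call. = FALSE)
  }
  if (flo > 0) {
    stop(sprintf("%s %.4g already exceeded at the scenario baseline (%.4g)",
                 what, target, flo + target), call. = FALSE)
  }
  # bisect on log-ca (the Hill law is log-sensitive)
  llo <- log(lo); lhi <- log(hi)
  for (i in 1:60) {
    mid <- exp((llo + lhi) / 2)
    fm <- f(mid)
    if (abs(fm) <= tol * abs(target)) return(mid)
    if (fm < 0) llo <- log(mid) else lhi <- log(mid)
  }
  exp((llo + lhi) / 2)
}

#' Live-cell scenario: ATP transient followed by Triton X-100 lysis
#'
#' Resting baseline, an agonist (ATP)-evoked calcium transient at `atp_time`,
#' and a saturating calcium step at `triton_time` (detergent lysis exposes
#' the remaining aequorin to extracellular-level calcium, discharging the
#' pool completely). The amplitude of the ATP transient is solved by
#' bisection on its peak calcium level so that the fraction of the pool
#' consumed during the ATP window (`[atp_time, triton_time)`) equals
#' `atp_fraction`; by construction the generative discharge ratio is then
#' close to `atp_fraction / (1 - atp_fraction)`.
#'
#' @param pool the [aequorin_pool()] expressed by the culture.
#' @param atp_fraction target fraction of the pool consumed during the ATP
#'   window (0 < f < 1).
#' @param atp_time,triton_time,duration scenario timings (s), with
#'   `0 < atp_time < triton_time < duration`.
#' @param dt scenario grid step (s).
#' @param resting_ca,sat_ca resting and saturating calcium levels (M).
#' @param atp_tau_r,atp_tau_d rise/decay constants of the ATP transient (s).
#' @param oscillation optional list (`peak_ca`, `period`, `tau_r`, `tau_d`)
#'   adding spontaneous baseline oscillations before the ATP challenge.
#' @return A `ca_scenario` with attributes `atp_peak_ca` and
#'   `atp_fraction_achieved`.
#' @export
scenario_live_cell <- function(pool, atp_fraction, atp_time = 30,
                               triton_time = 210, duration = 450, dt = 0.01,
                               resting_ca = 1e-7, sat_ca = 1e-2,
                               atp_tau_r = 5, atp_tau_d = 20,
                               oscillation = NULL) {
  stopifnot(inherits(pool, "aequorin_pool"))
  if (!(0 < atp_time && atp_time < triton_time && triton_time < duration)) {
    stop("need 0 < atp_time < triton_time < duration", call. = FALSE)
  }
  if (!(atp_fraction > 0 && atp_fraction < 1)) {
    stop("'atp_fraction' must be in (0, 1)", call. = FALSE)
  }
  base_seg <- if (is.null(oscillation)) {
    seg_constant(0, resting_ca)
  } else {
    seg_oscillation(0, resting_ca, oscillation$peak_ca,
                    period = oscillation$period %||% 20,
                    tau_r = oscillation$tau_r %||% 1,
                    tau_d = oscillation$tau_d %||% 4)
  }
  build <- function(peak) {
    ca_scenario(
      list(base_seg,
           seg_transient(atp_time, resting_ca, peak, atp_tau_r, atp_tau_d),
           seg_constant(triton_time, sat_ca)),
      duration = duration, dt = dt,
      provenance = sprintf("live cell: ATP at %g s, Triton at %g s", atp_time,
                           triton_time)
    )
  }
  frac <- function(profile) {
    n <- profile$n_remaining
    t <- profile$t
    (n[which.min(abs(t - atp_time))] - n[which.min(abs(t - triton_time))]) /
      profile$n_total
  }
  peak <- solve_ca(pool, build, frac, atp_fraction,
                   lo = resting_ca, hi = sat_ca, tol = 1e-4,
                   what = "ATP consumed fraction")
  sc <- build(peak)
  attr(sc, "atp_peak_ca") <- peak
  attr(sc, "atp_fraction_achieved") <- frac(emit(pool, sc))
  sc
}

#' Mitochondrial-uptake transient scenario
#'
#' A single fast rise--decay calcium transient (mitochondrial matrix calcium
#' uptake after agonist stimulation) whose peak calcium is solved so that the
#' peak expected photoelectron rate equals `peak_rate` (default 2.2 MHz, a
#' signal well below the megahertz pile-up regime in counting mode).
#'
#' @param pool the [aequorin_pool()].
#' @param peak_rate target peak emission rate (Hz).
#' @param t0 transient onset (s).
#' @param tau_r,tau_d rise/decay constants (s).
#' @param duration,dt scenario grid.
#' @param resting_ca,sat_ca resting and saturating calcium (M).
#' @return A `ca_scenario` with attribute `peak_ca`.
#' @export
scenario_mito <- function(pool, peak_rate = 2.2e6, t0 = 30, tau_r = 2,
                          tau_d = 8, duration = 90, dt = 0.01,
                          resting_ca = 1e-7, sat_ca = 1e-2) {
  stopifnot(inherits(pool, "aequorin_pool"))
  stop_if_not_scalar_number(peak_rate, "peak_rate", lower = 0, strict = TRUE)
  build <- function(peak) {
    ca_scenario(
      list(seg_constant(0, resting_ca),
           seg_transient(t0, resting_ca, peak, tau_r, tau_d)),
      duration = duration, dt = dt,
      provenance = sprintf("mitochondrial uptake transient, target peak %.3g Hz",
                           peak_rate)
    )
  }
  peak_ca <- solve_ca(pool, build, function(p) max(p$rate), peak_rate,
                      lo = resting_ca, hi = sat_ca, what = "peak rate")
  sc <- build(peak_ca)
  attr(sc, "peak_ca") <- peak_ca
  sc
}

#' Spontaneous sub-50-kHz calcium oscillation scenario
#'
#' A periodic train of small rise--decay calcium events whose per-event peak
#' emission rate is solved to `peak_rate`. Spontaneous cytosolic oscillations
#' sit below 50 kHz at the sensor, so `peak_rate` is capped there.
#'
#' @param pool the [aequorin_pool()].
#' @param peak_rate target per-event peak emission rate (Hz, < 50 kHz).
#' @param period oscillation period (s).
#' @param tau_r,tau_d per-event rise/decay constants (s).
#' @param duration,dt scenario grid.
#' @param resting_ca,sat_ca resting and saturating calcium (M).
#' @return A `ca_scenario` with attribute `peak_ca`.
#' @export
scenario_oscillations <- function(pool, peak_rate = 3e4, period = 20,
                                  tau_r = 1, tau_d = 4, duration = 120,
                                  dt = 0.01, resting_ca = 1e-7,
                                  sat_ca = 1e-2) {
  stopifnot(inherits(pool, "aequorin_pool"))
  if (peak_rate >= 5e4) {
    stop("spontaneous oscillations are a sub-50-kHz regime; 'peak_rate' must be < 50 kHz",
         call. = FALSE)
  }
  build <- function(peak) {
    ca_scenario(
      list(seg_oscillation(0, resting_ca, peak, period = period,
                           tau_r = tau_r, tau_d = tau_d)),
      duration = duration, dt = dt,
      provenance = sprintf("spontaneous oscillations, period %g s", period)
    )
  }
  peak_ca <- solve_ca(pool, build, function(p) max(p$rate), peak_rate,
                      lo = resting_ca, hi = sat_ca, what = "peak rate")
  sc <- build(peak_ca)
  attr(sc, "peak_ca") <- peak_ca
  sc
}
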