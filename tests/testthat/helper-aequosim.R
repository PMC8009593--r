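# Shared fixture builders. All fixtures are generated in code.

# scenario holding calcium at a saturating level for the whole duration
sat_scenario <- function(duration = 12, dt = 0.01, ca = 1e-2) {
  ca_scenario(list(seg_constant(0, ca)), duration = duration, dt = dt)
}

# hand-built event-mode arrival stream
event_stream <- function(times, span = c(0, max(times, 0.1))) {
  structure(
    list(mode = "event_list", times = times, counted = FALSE, seed = NULL,
         span = span),
    class = "arrival_stream"
  )
}

# hand-built count trace (already baseline-subtracted for analytic checks)
make_count_trace <- function(freq, window = 0.1, baseline_subtracted = TRUE) {
  out <- data.frame(
    t = (seq_along(freq) - 1) * window,
    counts = freq * window,
    freq = freq,
    saturated = rep(FALSE, length(freq))
  )
  class(out) <- c("count_trace", "data.frame")
  attr(out, "window") <- window
  attr(out, "baseline_subtracted") <- baseline_subtracted
  out
}

# counted-rate net oracle: what the discriminator reads above its own dark
# baseline when signal at rate L rides on dark at rate D (paralyzable)
net_counted <- function(L, D, tau) {
  (L + D) * exp(-(L + D) * tau) - D * exp(-D * tau)
}
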