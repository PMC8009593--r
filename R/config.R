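#' SPC detector configuration
#'
#' Parameters of the single-photon-counting branch: a SiPM viewed through a
#' shaped single-photoelectron pulse, a leading-edge discriminator and a
#' windowed scaler.
#'
#' The effective dead time equals the full shaped-pulse duration (30 ns after
#' zero-pole cancellation). The 50% discriminator threshold affects only the
#' dead-time behaviour, not single-event efficiency: an isolated
#' single-photoelectron pulse always crosses half of its own amplitude.
#'
#' Event-level simulation is exact but costs one random variate per arrival;
#' recordings whose expected arrival count is very large (bright lysis
#' bursts, or megahertz dark rates sustained for minutes) are switched to a
#' binned regime in which per-bin Poisson counts are drawn and dead-time
#' losses are applied through the closed-form counted-rate law. The switch
#' triggers when the peak total rate exceeds `hybrid_threshold` or when the
#' expected total number of arrivals exceeds `hybrid_max_events`.
#'
#' @param dcr dark-count rate (Hz). Default 904 kHz, a room-temperature
#'   megahertz-class 6x6 mm device.
#' @param pulse_tau effective shaped-pulse duration = dead time (s).
#' @param deadtime_model `"paralyzable"` (default: overlapping pulses
#'   re-extend the occupancy seen by a leading-edge discriminator) or
#'   `"nonparalyzable"`.
#' @param discriminator_threshold leading-edge threshold as a fraction of the
#'   single-photoelectron amplitude, in (0, 1).
#' @param hybrid_threshold total rate (Hz) above which arrival sampling is
#'   binned.
#' @param hybrid_max_events expected arrival count above which arrival
#'   sampling is binned.
#' @param scaler_bits counter depth of the windowed scaler; counts clip at
#'   `2^scaler_bits - 1`.
#' @param seed optional root seed; every stochastic operation derives an
#'   independent, reproducible substream from it.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(dcr = 904e3, pulse_tau = 30e-9,
                            deadtime_model = c("paralyzable", "nonparalyzable"),
                            discriminator_threshold = 0.5,
                            hybrid_threshold = 5e6, hybrid_max_events = 5e6,
                            scaler_bits = 32, seed = NULL) {
  stop_if_not_scalar_number(dcr, "dcr", lower = 0)
  stop_if_not_scalar_number(pulse_tau, "pulse_tau", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(discriminator_threshold, "discriminator_threshold")
  if (discriminator_threshold <= 0 || discriminator_threshold >= 1) {
    stop("'discriminator_threshold' must be in (0, 1)", call. = FALSE)
  }
  deadtime_model <- match.arg(deadtime_model)
  structure(
    list(dcr = dcr, pulse_tau = pulse_tau, deadtime_model = deadtime_model,
         discriminator_threshold = discriminator_threshold,
         hybrid_threshold = hybrid_threshold,
         hybrid_max_events = hybrid_max_events,
         scaler_bits = scaler_bits, seed = seed),
    class = "detector_config"
  )
}

#' QDC charge-integration configuration
#'
#' Parameters of the charge-integration branch: a gated analog integrator
#' (QDC) sampling the low-gain amplifier output. Per gate, the integrated
#' charge is the detected photoelectron count times `charge_per_pe`, plus
#' white Gaussian electronic noise, an optional slow baseline random walk,
#' and a pedestal; the result is quantized to ADC channels.
#'
#' Defaults: 5 us gate repeating at 11.2 kHz, 272 fC per photoelectron
#' (sensor datasheet conversion), 5600-sample block averaging (2 Hz trace
#' granularity), 12-bit ADC with a 50-channel pedestal. `adc_gain` (80 fC per
#' channel) leaves headroom for a ~100-200 MHz lysis burst within the 12-bit
#' range; the 2.5x-10x amplifier gain of the front end is absorbed into it.
#' `noise_sigma` (0.7 pC per gate) is calibrated so the single-gate empirical
#' limit of detection sits near 2 MHz, i.e. electronic noise comparable to,
#' and slightly above, the Poisson dark-charge fluctuation.
#'
#' @param gate integration gate (s), valid between 4 and 32 us.
#' @param charge_per_pe charge per photoelectron (C).
#' @param sampling_rate gate repetition rate (Hz); `sampling_rate * gate`
#'   must not exceed 1.
#' @param block default block size for trace averaging.
#' @param pedestal baseline offset (ADC channels).
#' @param adc_gain charge per ADC channel (C/channel).
#' @param adc_bits quantizer depth.
#' @param noise_sigma white Gaussian charge noise per gate (C).
#' @param drift_sigma per-gate step of an optional baseline random walk (C);
#'   0 (default) disables drift.
#' @param seed optional root seed for the channel's random substreams.
#' @return An object of class `qdc_config`.
#' @export
qdc_config <- function(gate = 5e-6, charge_per_pe = 272e-15,
                       sampling_rate = 11.2e3, block = 5600, pedestal = 50,
                       adc_gain = 80e-15, adc_bits = 12, noise_sigma = 0.7e-12,
                       drift_sigma = 0, seed = NULL) {
  stop_if_not_scalar_number(gate, "gate", lower = 0, strict = TRUE)
  if (gate < 4e-6 || gate > 32e-6) {
    stop("'gate' must lie in the supported range [4 us, 32 us]", call. = FALSE)
  }
  stop_if_not_scalar_number(charge_per_pe, "charge_per_pe", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", lower = 0, strict = TRUE)
  if (sampling_rate * gate > 1) {
    stop("'sampling_rate' * 'gate' must be <= 1 (gates cannot overlap)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(block, "block", lower = 1)
  stop_if_not_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  stop_if_not_scalar_number(drift_sigma, "drift_sigma", lower = 0)
  structure(
    list(gate = gate, charge_per_pe = charge_per_pe,
         sampling_rate = sampling_rate, block = block, pedestal = pedestal,
         adc_gain = adc_gain, adc_bits = adc_bits, noise_sigma = noise_sigma,
         drift_sigma = drift_sigma, seed = seed),
    class = "qdc_config"
  )
}
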