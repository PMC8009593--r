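#' Simulate the gated charge-integration branch
#'
#' One gate opens every `1/sampling_rate` seconds and integrates the SiPM
#' output for `gate` seconds. Per gate, the detected photoelectron count is
#' Poisson with mean `gate * (L(t) + dcr)`; the charge is the count times
#' `charge_per_pe` plus white Gaussian electronic noise, an optional baseline
#' random walk, and the pedestal, then quantized to ADC channels with
#' clipping. Charge integration sees no dead-time loss, which is what makes
#' it usable far into the tens-of-megahertz regime where counting saturates.
#'
#' The photoelectron-equivalent column is derived from the recorded
#' (quantized) charge via [charge_to_photons()].
#'
#' @param profile an `emission_profile`.
#' @param det a [detector_config()] (supplies the dark-count rate).
#' @param qdc a [qdc_config()].
#' @return A `charge_trace`: data frame with columns `t` (gate start, s),
#'   `adc` (channels), `charge` (C, quantized), `pe_equiv` and `saturated`,
#'   with attributes `gate`, `charge_per_pe`, `sampling_rate`,
#'   `pedestal_charge`, `block` (= 1), `sample_dt` and
#'   `baseline_subtracted`.
#' @export
integrate_gates <- function(profile, det = detector_config(),
                            qdc = qdc_config()) {
  stopifnot(inherits(profile, "emission_profile"),
            inherits(det, "detector_config"), inherits(qdc, "qdc_config"))
  span <- range(profile$t)
  n <- floor((span[2] - span[1] - qdc$gate) * qdc$sampling_rate) + 1
  if (n < 1L) stop("profile does not cover a single integration gate", call. = FALSE)
  t_gate <- span[1] + (seq_len(n) - 1) / qdc$sampling_rate
  rate <- profile_rate_at(profile, t_gate + qdc$gate / 2) + det$dcr
  pedestal_charge <- qdc$pedestal * qdc$adc_gain
  charge <- with_substream(qdc$seed, 3L, {
    pe <- stats::rpois(n, qdc$gate * rate)
    ch <- pe * qdc$charge_per_pe + pedestal_charge
    if (qdc$noise_sigma > 0) ch <- ch + stats::rnorm(n, 0, qdc$noise_sigma)
    if (qdc$drift_sigma > 0) ch <- ch + cumsum(stats::rnorm(n, 0, qdc$drift_sigma))
    ch
  })
  cap <- 2^qdc$adc_bits - 1
  adc_raw <- round(charge / qdc$adc_gain)
  saturated <- adc_raw > cap | adc_raw < 0
  adc <- pmin(pmax(adc_raw, 0), cap)
  charge_rec <- adc * qdc$adc_gain
  out <- data.frame(
    t = t_gate,
    adc = adc,
    charge = charge_rec,
    pe_equiv = (charge_rec - pedestal_charge) / qdc$charge_per_pe,
    saturated = saturated
  )
  class(out) <- c("charge_trace", "data.frame")
  attr(out, "gate") <- qdc$gate
  attr(out, "charge_per_pe") <- qdc$charge_per_pe
  attr(out, "sampling_rate") <- qdc$sampling_rate
  attr(out, "pedestal_charge") <- pedestal_charge
  attr(out, "block") <- 1L
  attr(out, "sample_dt") <- 1 / qdc$sampling_rate
  attr(out, "baseline_subtracted") <- FALSE
  out
}

#' Block-average a charge trace
#'
#' Non-overlapping means of `block` consecutive gates (the averaging the
#' acquisition system applies to raise sensitivity: 5600 samples at 11.2 kHz
#' gives a 2 Hz trace). A trailing partial block is dropped. A block is
#' flagged saturated if any member gate was.
#'
#' @param trace a `charge_trace`.
#' @param block block size (>= 1); must not exceed the trace length.
#' @return The averaged `charge_trace` (attributes `block` and `sample_dt`
#'   updated).
#' @export
block_average <- function(trace, block) {
  stopifnot(inherits(trace, "charge_trace"))
  stop_if_not_scalar_number(block, "block", lower = 1)
  block <- as.integer(block)
  n <- nrow(trace)
  if (block > n) stop("'block' exceeds the trace length", call. = FALSE)
  if (block == 1L) return(trace)
  m <- (n %/% block) * block
  fold <- function(x) colMeans(matrix(x[seq_len(m)], nrow = block))
  out <- data.frame(
    t = fold(trace$t),
    adc = fold(trace$adc),
    charge = fold(trace$charge),
    pe_equiv = fold(trace$pe_equiv),
    saturated = colSums(matrix(trace$saturated[seq_len(m)], nrow = block)) > 0
  )
  class(out) <- c("charge_trace", "data.frame")
  for (a in c("gate", "charge_per_pe", "sampling_rate", "pedestal_charge",
              "baseline_subtracted")) {
    attr(out, a) <- attr(trace, a)
  }
  attr(out, "block") <- attr(trace, "block") * block
  attr(out, "sample_dt") <- attr(trace, "sample_dt") * block
  out
}

#' Convert integrated charge to photoelectron equivalents (and back)
#'
#' `charge_to_photons()` maps a charge above pedestal to photoelectrons via
#' the datasheet conversion factor (272 fC per photoelectron by default):
#' `(charge - pedestal_charge) / charge_per_pe`. Linear and invertible;
#' `photons_to_charge()` is the inverse.
#'
#' @param charge charge value(s) in C.
#' @param photons photoelectron-equivalent value(s).
#' @param qdc a [qdc_config()].
#' @return Numeric vector.
#' @export
charge_to_photons <- function(charge, qdc = qdc_config()) {
  (charge - qdc$pedestal * qdc$adc_gain) / qdc$charge_per_pe
}

#' @rdname charge_to_photons
#' @export
photons_to_charge <- function(photons, qdc = qdc_config()) {
  photons * qdc$charge_per_pe + qdc$pedestal * qdc$adc_gain
}

#' Write / read a charge trace as a delimited text table
#'
#' Tab-separated columns `t_s`, `adc`, `charge_pC`, `pe_equiv`, `saturated`
#' with commented header lines carrying the gate, conversion factor,
#' sampling rate and block size.
#'
#' @param trace a `charge_trace`.
#' @param path file path.
#' @export
write_charge_trace <- function(trace, path) {
  stopifnot(inherits(trace, "charge_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# aequosim charge trace",
    sprintf("# gate_s: %.15g", attr(trace, "gate")),
    sprintf("# charge_per_pe_C: %.15g", attr(trace, "charge_per_pe")),
    sprintf("# sampling_rate_hz: %.15g", attr(trace, "sampling_rate")),
    sprintf("# pedestal_charge_C: %.15g", attr(trace, "pedestal_charge")),
    sprintf("# block: %d", attr(trace, "block")),
    "t_s\tadc\tcharge_pC\tpe_equiv\tsaturated"), con)
  utils::write.table(
    data.frame(trace$t, trace$adc, trace$charge * 1e12, trace$pe_equiv,
               as.integer(trace$saturated)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_charge_trace
#' @export
read_charge_trace <- function(path) {
  header <- readLines(path, n = 8L)
  grab <- function(key) {
    as.numeric(sub(paste0("^# ", key, ": "), "",
                   grep(paste0("^# ", key, ": "), header, value = TRUE)))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- data.frame(t = d$t_s, adc = d$adc, charge = d$charge_pC * 1e-12,
                    pe_equiv = d$pe_equiv, saturated = as.logical(d$saturated))
  class(out) <- c("charge_trace", "data.frame")
  attr(out, "gate") <- grab("gate_s")
  attr(out, "charge_per_pe") <- grab("charge_per_pe_C")
  attr(out, "sampling_rate") <- grab("sampling_rate_hz")
  attr(out, "pedestal_charge") <- grab("pedestal_charge_C")
  attr(out, "block") <- as.integer(grab("block"))
  attr(out, "sample_dt") <- attr(out, "block") / attr(out, "sampling_rate")
  attr(out, "baseline_subtracted") <- FALSE
  out
}
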