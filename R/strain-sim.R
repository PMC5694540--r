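#' Parameters for the synthetic strain-trace generator
#'
#' Defaults emulate the statistical structure of the instrumented-feeder
#' recordings: a licking band (10-15 Hz) and a wingbeat band (35-45 Hz)
#' present only while the bird is docked, continuous 60 Hz mains pickup,
#' slow linear drift, docking/undocking spike transients, a mean push offset
#' while docked, and white sensor noise. Amplitudes are in volts at the
#' amplifier output; the push offset is expressed in gram-equivalents and
#' converted through the calibration slope.
#'
#' @param sample_rate Sampling rate (Hz), default 1000.
#' @param pre_s Seconds of recording before the first dock (>= 3).
#' @param post_s Seconds of recording after the last dock (>= 3).
#' @param dock_intervals List of `c(start, end)` dock intervals (s).
#' @param push_offset_g Length-2 signed push in gram-equivalents,
#'   `c(horizontal, vertical)`; positive = left / up.
#' @param licking_amp,licking_freq Licking component amplitude (V) and
#'   frequency (Hz, 10-15).
#' @param wingbeat_amp,wingbeat_freq Wingbeat component amplitude (V) and
#'   frequency (Hz, 35-45).
#' @param mains_amp Continuous 60 Hz mains amplitude (V).
#' @param drift_slope Linear drift (V/s), applied to both channels.
#' @param spike_amp Dock/undock transient amplitude (V).
#' @param noise_sd White noise s.d. (V).
#' @param calibration_slope Length-2 calibration slope (V/g),
#'   `c(horizontal, vertical)`.
#' @param seed Integer seed.
#' @return A list of class `strain_sim_params`.
#' @export
strain_sim_params <- function(sample_rate = 1000,
                              pre_s = 4,
                              post_s = 4,
                              dock_intervals = list(c(4.5, 9.5)),
                              push_offset_g = c(0.32, 0.2),
                              licking_amp = 0.05, licking_freq = 12,
                              wingbeat_amp = 0.15, wingbeat_freq = 40,
                              mains_amp = 0.02,
                              drift_slope = 0.005,
                              spike_amp = 1,
                              noise_sd = 0.01,
                              calibration_slope = c(0.159, 0.164),
                              seed = 1L) {
  if (pre_s < 3 || post_s < 3) stopf("pre_s and post_s must each be >= 3 s")
  fmax <- max(licking_freq, wingbeat_freq, 60)
  if (sample_rate <= 2 * fmax) stopf("sample_rate must exceed twice the highest injected frequency")
  push_offset_g <- rep_len(push_offset_g, 2L)
  calibration_slope <- rep_len(calibration_slope, 2L)
  structure(as.list(environment()), class = "strain_sim_params")
}

#' Generate a synthetic two-channel strain trace
#'
#' @param params A [strain_sim_params()] object.
#' @return A [strain_trace()].
#' @examples
#' tr <- simulate_strain_trace(strain_sim_params(seed = 7))
#' @export
simulate_strain_trace <- function(params = strain_sim_params()) {
  stopifnot(inherits(params, "strain_sim_params"))
  p <- params
  docks <- p$dock_intervals
  if (length(docks) == 0L) stopf("at least one dock interval is required")
  starts <- vapply(docks, `[`, 0, 1L)
  ends <- vapply(docks, `[`, 0, 2L)
  if (min(starts) < p$pre_s) stopf("dock intervals must start after pre_s")
  t_end <- max(ends) + p$post_s
  fs <- p$sample_rate
  t <- seq(0, t_end, by = 1 / fs)
  n <- length(t)

  docked <- rep(FALSE, n)
  for (d in docks) docked <- docked | (t >= d[1L] & t <= d[2L])

  base <- p$drift_slope * t + p$mains_amp * sin(2 * pi * 60 * t)
  feeding <- p$licking_amp * sin(2 * pi * p$licking_freq * t) +
    p$wingbeat_amp * sin(2 * pi * p$wingbeat_freq * t)

  # one-sided exponential transient at each dock/undock, alternating sign
  spikes <- rep(0, n)
  if (p$spike_amp != 0) {
    for (d in docks) {
      for (k in 1:2) {
        t0 <- d[k]
        idx <- which(t >= t0 & t < t0 + 0.1)
        spikes[idx] <- spikes[idx] +
          (if (k == 1L) 1 else -1) * p$spike_amp * exp(-(t[idx] - t0) / 0.02)
      }
    }
  }

  with_seed(p$seed, {
    mk_channel <- function(axis) {
      v <- base + spikes
      v[docked] <- v[docked] + feeding[docked] +
        p$push_offset_g[axis] * p$calibration_slope[axis]
      if (p$noise_sd > 0) v <- v + stats::rnorm(n, sd = p$noise_sd)
      v
    }
    h <- mk_channel(1L)
    v <- mk_channel(2L)
    strain_trace(t, h, v, docks)
  })
}

#' Generate a synthetic calibration recording
#'
#' Emulates hanging known weights from the feeder with the sensor reoriented
#' for the axis under calibration: voltage = slope x mass + noise.
#'
#' @param slope_V_per_g True calibration slope (V/g).
#' @param weights_g Calibration masses (g), default `c(2, 5, 10)`.
#' @param noise_sd Voltage noise s.d. (V).
#' @param n_reps Repeats per weight.
#' @param seed Integer seed.
#' @return Data frame with columns `mass_g`, `voltage_V`.
#' @export
simulate_calibration <- function(slope_V_per_g, weights_g = c(2, 5, 10),
                                 noise_sd = 0, n_reps = 1L, seed = NULL) {
  if (any(weights_g <= 0)) stopf("weights must be positive")
  m <- rep(weights_g, each = n_reps)
  with_seed(seed, {
    v <- slope_V_per_g * m
    if (noise_sd > 0) v <- v + stats::rnorm(length(m), sd = noise_sd)
    data.frame(mass_g = m, voltage_V = v)
  })
}
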