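#' Fit a through-origin calibration line
#'
#' Calibration recordings relate hung mass to amplified bridge voltage; the
#' fit is constrained through the origin, so the least-squares slope is
#' `sum(m * v) / sum(m^2)`.
#'
#' @param pairs Data frame with columns `mass_g` and `voltage_V` (as from
#'   [simulate_calibration()]), or a two-column matrix.
#' @return An object of class `calibration_fit`: list with `slope` (V/g) and
#'   `residual_rms` (V).
#' @examples
#' fit_calibration(simulate_calibration(0.159))
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1L) stopf("at least one mass/voltage pair is required")
  m <- pairs[[1L]]
  v <- pairs[[2L]]
  if (any(m <= 0)) stopf("masses must be positive")
  slope <- sum(m * v) / sum(m^2)
  res <- v - slope * m
  structure(list(slope = slope, residual_rms = sqrt(mean(res^2))),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope %.4f V/g, residual RMS %.4g V\n",
              x$slope, x$residual_rms))
  invisible(x)
}

#' Segment the feeding portions of a strain trace
#'
#' Each dock event yields one feed segment, conservatively cropped by
#' `crop_s` on either end to eliminate the docking/undocking signal spikes.
#' The pre-feed baseline window ends `crop_s` before the first dock start
#' and the post-feed window starts `crop_s` after the last dock end, so the
#' same guard shields the baseline from the transients; feeds whose crop
#' would empty them are flagged degenerate and excluded from analysis.
#'
#' @param trace A [strain_trace()].
#' @param crop_s Seconds cropped from each end of every dock (default 0.25).
#' @param min_window_s Minimum required pre/post window length (default 3).
#' @return Data frame with one row per dock: `feed`, `dock_start`,
#'   `dock_end`, `crop_start`, `crop_end`, `degenerate`; attributes
#'   `pre_window` and `post_window` hold `c(start, end)` in seconds.
#' @export
segment_feeds <- function(trace, crop_s = 0.25, min_window_s = 3) {
  stopifnot(inherits(trace, "strain_trace"))
  dk <- docks(trace)
  if (length(dk) == 0L) stopf("trace has no dock events")
  starts <- vapply(dk, `[`, 0, 1L)
  ends <- vapply(dk, `[`, 0, 2L)
  seg <- data.frame(feed = seq_along(dk), dock_start = starts,
                    dock_end = ends, crop_start = starts + crop_s,
                    crop_end = ends - crop_s)
  seg$degenerate <- seg$crop_end <= seg$crop_start
  # the pre/post baseline windows carry the same crop guard at their
  # dock-adjacent edges, so docking/undocking transients touch neither the
  # feed segments nor the baseline
  pre <- c(min(trace$time_s), min(starts) - crop_s)
  post <- c(max(ends) + crop_s, max(trace$time_s))
  if (min(starts) - min(trace$time_s) < min_window_s) {
    stopf("only %.2f s of recording before the first feed; need >= %.2f s",
          min(starts) - min(trace$time_s), min_window_s)
  }
  if (max(trace$time_s) - max(ends) < min_window_s) {
    stopf("only %.2f s of recording after the last feed; need >= %.2f s",
          max(trace$time_s) - max(ends), min_window_s)
  }
  attr(seg, "pre_window") <- pre
  attr(seg, "post_window") <- post
  seg
}

window_samples <- function(trace, window, channel) {
  trace[[channel]][trace$time_s >= window[1L] & trace$time_s <= window[2L]]
}

#' Detrend a strain trace against its pre- and post-feed baseline
#'
#' Fits an ordinary least-squares line (slope and intercept) to the
#' concatenated pre- and post-feed samples of each channel and subtracts it
#' from the whole channel, removing amplifier drift without touching the
#' docked-segment content.
#'
#' @param trace A [strain_trace()].
#' @param segments Output of [segment_feeds()].
#' @return A detrended [strain_trace()].
#' @export
detrend_trace <- function(trace, segments) {
  stopifnot(inherits(trace, "strain_trace"))
  pre <- attr(segments, "pre_window")
  post <- attr(segments, "post_window")
  sel <- (trace$time_s >= pre[1L] & trace$time_s <= pre[2L]) |
    (trace$time_s >= post[1L] & trace$time_s <= post[2L])
  if (!any(sel)) stopf("empty pre/post baseline windows")
  out <- trace
  for (ch in c("horizontal_V", "vertical_V")) {
    fit <- stats::lm.fit(cbind(1, trace$time_s[sel]), trace[[ch]][sel])
    out[[ch]] <- trace[[ch]] - (fit$coefficients[1L] +
                                  fit$coefficients[2L] * trace$time_s)
  }
  out
}

#' Peak-to-peak amplitude ratio, docked over pre-dock
#'
#' Ratio of the peak-to-peak signal amplitude while the bird is docked
#' (cropped feed segment) to the pre-dock value; values above 1 indicate
#' that docking increased the signal amplitude.
#'
#' @param x_docked Detrended channel samples in the cropped feed segment.
#' @param x_pre Detrended channel samples in the pre-dock window.
#' @return Dimensionless ratio.
#' @export
amplitude_ratio <- function(x_docked, x_pre) {
  pp_pre <- diff(range(x_pre))
  if (pp_pre == 0) stopf("pre-dock peak-to-peak amplitude is zero")
  diff(range(x_docked)) / pp_pre
}

#' Band spectral-power ratio, docked over pre-dock
#'
#' Integrated Welch PSD over a frequency band, compared between the docked
#' (cropped feed) and pre-dock portions of a channel. Used with the licking
#' (10-15 Hz), wingbeat (35-45 Hz), and mains (59-61 Hz) bands.
#'
#' @param x_docked,x_pre Channel samples (each >= 1 s).
#' @param fs Sampling rate (Hz).
#' @param band Length-2 band limits (Hz); must lie below the Nyquist rate.
#' @return Dimensionless power ratio.
#' @export
band_power_ratio <- function(x_docked, x_pre, fs, band) {
  if (max(band) >= fs / 2) stopf("band exceeds the Nyquist frequency")
  if (length(x_docked) < fs || length(x_pre) < fs) {
    stopf("docked and pre-dock windows must each be >= 1 s")
  }
  band_power(welch_psd(x_docked, fs), band) /
    band_power(welch_psd(x_pre, fs), band)
}

#' Mean push against the feeder, in body weights
#'
#' The push is the shift in the signal mean between feeding and pre-feeding,
#' converted to gram-equivalents through the calibration slope and
#' normalized to body weight. Positive values indicate a push to the left
#' (horizontal axis) or upward (vertical axis).
#'
#' @param x_docked,x_pre Detrended channel samples.
#' @param slope Calibration slope (V/g), > 0.
#' @param body_mass_g Body mass used for normalization (g); 4.0 g for the
#'   instrumented-feeder experiment.
#' @return Signed push in body weights (wb).
#' @export
compute_push <- function(x_docked, x_pre, slope, body_mass_g = 4) {
  if (slope <= 0) stopf("calibration slope must be positive")
  (mean(x_docked) - mean(x_pre)) / slope / body_mass_g
}

#' Full strain-signal analysis of one trial
#'
#' Runs the feeder-force pipeline on a two-channel trace: feed segmentation
#' with cropping, baseline detrending, then per-feed amplitude ratio, band
#' power ratios (licking 10-15 Hz, wingbeat 35-45 Hz, mains 59-61 Hz) and
#' push in body weights for each axis. The vertical channel is processed
#' identically to the horizontal one but carries a quality flag, reflecting
#' the less reliable vertical calibration typical of such rigs.
#'
#' @param trace A [strain_trace()].
#' @param calibration Length-2 list of [fit_calibration()] results (or
#'   numeric slopes), `c(horizontal, vertical)`.
#' @param body_mass_g Normalizing body mass (g), default 4.0.
#' @param crop_s Crop applied to each dock end (s), default 0.25.
#' @return List with `feeds` (per-feed, per-axis data frame with columns
#'   `feed`, `axis`, `amplitude_ratio`, `bpr_10_15`, `bpr_35_45`, `bpr_60`,
#'   `push_wb`, `quality`) and `trial` (per-axis means across feeds).
#' @export
analyze_strain <- function(trace, calibration, body_mass_g = 4,
                           crop_s = 0.25) {
  stopifnot(inherits(trace, "strain_trace"))
  slopes <- vapply(calibration, function(cc) {
    if (inherits(cc, "calibration_fit")) cc$slope else as.numeric(cc)
  }, 0)
  slopes <- rep_len(slopes, 2L)
  fs <- sample_rate(trace)
  seg <- segment_feeds(trace, crop_s = crop_s)
  det <- detrend_trace(trace, seg)
  pre <- attr(seg, "pre_window")
  bands <- list(bpr_10_15 = c(10, 15), bpr_35_45 = c(35, 45),
                bpr_60 = c(59, 61))
  axes <- c(horizontal = "horizontal_V", vertical = "vertical_V")
  rows <- list()
  for (i in which(!seg$degenerate)) {
    win <- c(seg$crop_start[i], seg$crop_end[i])
    for (a in seq_along(axes)) {
      xd <- window_samples(det, win, axes[[a]])
      xp <- window_samples(det, pre, axes[[a]])
      bp <- vapply(bands, function(b) band_power_ratio(xd, xp, fs, b), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        feed = seg$feed[i], axis = names(axes)[a],
        amplitude_ratio = amplitude_ratio(xd, xp),
        bpr_10_15 = bp[[1L]], bpr_35_45 = bp[[2L]], bpr_60 = bp[[3L]],
        push_wb = compute_push(xd, xp, slopes[a], body_mass_g),
        quality = if (names(axes)[a] == "vertical") "flagged" else "ok")
    }
  }
  feeds <- do.call(rbind, rows)
  num <- c("amplitude_ratio", "bpr_10_15", "bpr_35_45", "bpr_60", "push_wb")
  trial <- do.call(rbind, lapply(split(feeds, feeds$axis), function(d) {
    cbind(data.frame(axis = d$axis[1L], n_feeds = nrow(d)),
          as.data.frame(as.list(colMeans(d[num]))))
  }))
  rownames(trial) <- NULL
  list(feeds = feeds, trial = trial)
}
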