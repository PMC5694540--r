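#' Parameters for the synthetic wingbeat-kinematics generator
#'
#' Defaults for each flight mode follow the experimental trial means: a 39 Hz
#' wingbeat for hovering and 41 Hz for feeder tracking, a 48:52
#' downstroke:upstroke ratio, and per-mode wing bank angle (WBA), body
#' angle, travel angle, feeder speed and bill insertion values. During
#' feeder tracking the leading wing is elevated relative to the trailing
#' wing and its angle-of-attack reversal (supination rotation) is delayed
#' while the trailing wing's is advanced.
#'
#' @param mode `"hover"`, `"left"` or `"right"` (direction of feeder travel).
#' @param wingbeat_freq Wingbeat frequency (Hz); defaults to 39 (hover) or
#'   41 (tracking).
#' @param downstroke_fraction Fraction of the cycle spent in downstroke
#'   (default 0.48).
#' @param stroke_amplitude_deg Stroke amplitude Phi_sp (degrees, <= 180).
#' @param wba_ds,wba_us Target wing bank angle per stroke phase (degrees,
#'   positive = left wing elevated).
#' @param chi_xz_ds,chi_xz_us Lateral (sagittal-plane) body angle per phase
#'   (degrees above horizontal).
#' @param chi_yz_ds,chi_yz_us Frontal body angle per phase (degrees of
#'   dorsoventral-axis deviation from vertical, positive = tilt toward the
#'   bird's left).
#' @param alpha_mid_ds,alpha_mid_us Geometric angle of attack at mid-stroke
#'   (degrees; the wing is near 90 deg at stroke reversals).
#' @param alpha_shift Length-2 per-wing phase shift (fraction of a cycle)
#'   applied to the angle-of-attack schedule, `c(left, right)`; positive =
#'   delayed rotation.
#' @param travel_angle_deg Travel angle Psi (degrees, positive = facing the
#'   direction of motion); `NA` for hovering.
#' @param feeder_speed_m_s Lateral feeder speed (m/s): 0 or 0.15.
#' @param bill_insertion_pct Percent of the exposed culmen inside the feeder.
#' @param culmen_length_m Exposed culmen length (m).
#' @param noise_sd_m Gaussian positional noise s.d. (m) added to landmarks.
#' @param n_wingbeats Number of wingbeats to generate.
#' @param seed Integer seed.
#' @return A list of class `kinematic_sim_params`.
#' @export
kinematic_sim_params <- function(mode = c("hover", "left", "right"),
                                 wingbeat_freq = NULL,
                                 downstroke_fraction = 0.48,
                                 stroke_amplitude_deg = 150,
                                 wba_ds = NULL, wba_us = NULL,
                                 chi_xz_ds = NULL, chi_xz_us = NULL,
                                 chi_yz_ds = NULL, chi_yz_us = NULL,
                                 alpha_mid_ds = 45, alpha_mid_us = 45,
                                 alpha_shift = NULL,
                                 travel_angle_deg = NULL,
                                 feeder_speed_m_s = NULL,
                                 bill_insertion_pct = NULL,
                                 culmen_length_m = 0.020,
                                 noise_sd_m = 1e-4,
                                 n_wingbeats = 12L,
                                 seed = 1L) {
  mode <- match.arg(mode)
  def <- switch(mode,
    hover = list(f = 39, wba_ds = 0.0, wba_us = -0.6,
                 chi_xz_ds = 66.8, chi_xz_us = 65.4,
                 chi_yz_ds = 0.2, chi_yz_us = 0.2,
                 shift = c(0, 0), psi = NA_real_, speed = 0, bill = 19.8),
    left = list(f = 41, wba_ds = 4.0, wba_us = 7.9,
                chi_xz_ds = 59.1, chi_xz_us = 57.6,
                chi_yz_ds = 3.5, chi_yz_us = 2.6,
                shift = c(0.02, -0.02), psi = 21.9, speed = 0.15,
                bill = 24.8),
    right = list(f = 41, wba_ds = -2.6, wba_us = -7.4,
                 chi_xz_ds = 56.5, chi_xz_us = 54.5,
                 chi_yz_ds = -1.8, chi_yz_us = -1.3,
                 shift = c(-0.02, 0.02), psi = -10.3, speed = 0.15,
                 bill = 27.7))
  take <- function(x, d) if (is.null(x)) d else x
  p <- list(
    mode = mode,
    wingbeat_freq = take(wingbeat_freq, def$f),
    downstroke_fraction = downstroke_fraction,
    stroke_amplitude_deg = stroke_amplitude_deg,
    wba_ds = take(wba_ds, def$wba_ds), wba_us = take(wba_us, def$wba_us),
    chi_xz_ds = take(chi_xz_ds, def$chi_xz_ds),
    chi_xz_us = take(chi_xz_us, def$chi_xz_us),
    chi_yz_ds = take(chi_yz_ds, def$chi_yz_ds),
    chi_yz_us = take(chi_yz_us, def$chi_yz_us),
    alpha_mid_ds = alpha_mid_ds, alpha_mid_us = alpha_mid_us,
    alpha_shift = rep_len(take(alpha_shift, def$shift), 2L),
    travel_angle_deg = take(travel_angle_deg, def$psi),
    feeder_speed_m_s = take(feeder_speed_m_s, def$speed),
    bill_insertion_pct = take(bill_insertion_pct, def$bill),
    culmen_length_m = culmen_length_m,
    noise_sd_m = noise_sd_m,
    n_wingbeats = as.integer(n_wingbeats),
    seed = seed)
  if (p$downstroke_fraction <= 0 || p$downstroke_fraction >= 1) {
    stopf("downstroke_fraction must be in (0, 1)")
  }
  if (p$wingbeat_freq <= 0) stopf("wingbeat_freq must be positive")
  if (p$stroke_amplitude_deg <= 0 || p$stroke_amplitude_deg > 180) {
    stopf("stroke_amplitude_deg must be in (0, 180]")
  }
  if (abs(p$bill_insertion_pct) > 100) stopf("|bill_insertion_pct| must be <= 100")
  structure(p, class = "kinematic_sim_params")
}

# travel sign: +1 toward the bird's left (+y), -1 right, NA hover
travel_sign <- function(mode) {
  switch(mode, hover = NA_real_, left = 1, right = -1)
}

# global yaw of the bird (deg): travel angle is signed relative to the
# travel direction, so eta = sign(travel) * Psi
body_yaw_deg <- function(params) {
  s <- travel_sign(params$mode)
  if (is.na(s)) 0 else s * params$travel_angle_deg
}

# Continuous per-phase waveforms used by both the landmark generator and the
# parametric wingbeat-cycle constructor. All return degrees; `ph` in [0, 1)
# with pronation at ph = 0 and supination at ph = downstroke_fraction.
wing_waveforms <- function(params) {
  p <- params
  d <- p$downstroke_fraction
  A <- p$stroke_amplitude_deg / 2

  excursion <- function(ph) {
    ph <- ph %% 1
    ifelse(ph < d,
           -A * cos(pi * ph / d),
           A * cos(pi * (ph - d) / (1 - d)))
  }

  # smooth periodic blend: +1 at mid-downstroke, -1 at mid-upstroke
  qblend <- function(ph) cos(2 * pi * ((ph %% 1) - d / 2))
  phg <- seq(0, 1, length.out = 4001L)[-4001L]
  qds <- mean(qblend(phg[phg < d]))
  qus <- mean(qblend(phg[phg >= d]))

  # solve (mean, swing) so that the phase means hit the ds/us targets
  blend_pair <- function(m_ds, m_us) {
    de <- (m_ds - m_us) / (qds - qus)
    list(bar = m_ds - de * qds, de = de)
  }

  elev_for <- function(target_ds, target_us) {
    cf <- blend_pair(target_ds, target_us)
    function(ph) cf$bar + cf$de * qblend(ph)
  }
  elev_left <- elev_for(p$wba_ds, p$wba_us)
  elev_right <- elev_for(-p$wba_ds, -p$wba_us)

  alpha_for <- function(shift) {
    function(ph) {
      phw <- (ph - shift) %% 1
      ifelse(phw < d,
             90 - (90 - p$alpha_mid_ds) * sin(pi * phw / d),
             90 - (90 - p$alpha_mid_us) * sin(pi * (phw - d) / (1 - d)))
    }
  }

  # body angles blend smoothly between their ds and us values
  chi_xz_cf <- blend_pair(p$chi_xz_ds, p$chi_xz_us)
  chi_yz_cf <- blend_pair(p$chi_yz_ds, p$chi_yz_us)

  list(
    excursion = excursion,
    elev = list(left = elev_left, right = elev_right),
    alpha = list(left = alpha_for(p$alpha_shift[1L]),
                 right = alpha_for(p$alpha_shift[2L])),
    chi_xz = function(ph) chi_xz_cf$bar + chi_xz_cf$de * qblend(ph),
    chi_yz = function(ph) chi_yz_cf$bar + chi_yz_cf$de * qblend(ph),
    # analytic sign of d(excursion)/dt: + during downstroke
    sweep_sign = function(ph) ifelse((ph %% 1) < d, 1, -1)
  )
}

#' Phase-normalized average wingbeat
#'
#' Builds a `wingbeat_cycle`: per-wing stroke-plane excursion, elevation and
#' geometric angle-of-attack traces at `n_points` equally spaced time points
#' over one wingbeat, with the first 48% of points labelled downstroke. This
#' parametric constructor evaluates the generator waveforms directly; the
#' same structure is produced from landmark data by [average_wingbeat()].
#'
#' @param params A [kinematic_sim_params()] object.
#' @param n_points Number of equally spaced time points (default 200).
#' @return An object of class `wingbeat_cycle`: list with `n`, elements
#'   `phi`, `elev`, `alpha` (each a list with `left`/`right` numeric
#'   vectors, degrees), `stroke` (factor `down`/`up`), `wingbeat_freq_hz`,
#'   `downstroke_fraction`, `stroke_amplitude_deg`, `v_body` (global m/s),
#'   `yaw_deg` and `mode`.
#' @examples
#' cyc <- wingbeat_cycle(kinematic_sim_params("hover"))
#' @export
wingbeat_cycle <- function(params, n_points = 200L) {
  stopifnot(inherits(params, "kinematic_sim_params"))
  n <- as.integer(n_points)
  if (n < 8L) stopf("n_points must be >= 8")
  wf <- wing_waveforms(params)
  ph <- (seq_len(n) - 1L) / n
  d <- params$downstroke_fraction
  s <- travel_sign(params$mode)
  v_body <- c(0, if (is.na(s)) 0 else s * params$feeder_speed_m_s, 0)
  cyc <- list(
    n = n,
    phase = ph,
    stroke = factor(ifelse(ph < d, "down", "up"), levels = c("down", "up")),
    phi = list(left = wf$excursion(ph), right = wf$excursion(ph)),
    elev = list(left = wf$elev$left(ph), right = wf$elev$right(ph)),
    alpha = list(left = wf$alpha$left(ph), right = wf$alpha$right(ph)),
    wingbeat_freq_hz = params$wingbeat_freq,
    downstroke_fraction = d,
    stroke_amplitude_deg = params$stroke_amplitude_deg,
    v_body = v_body,
    yaw_deg = body_yaw_deg(params),
    mode = params$mode)
  class(cyc) <- "wingbeat_cycle"
  validate_cycle(cyc)
}

validate_cycle <- function(cyc) {
  n <- cyc$n
  for (fld in c("phi", "elev", "alpha")) {
    for (w in c("left", "right")) {
      if (length(cyc[[fld]][[w]]) != n) {
        stopf("cycle field %s$%s must have exactly %d points", fld, w, n)
      }
    }
  }
  if (cyc$wingbeat_freq_hz <= 0) stopf("wingbeat frequency must be positive")
  cyc
}

#' @export
print.wingbeat_cycle <- function(x, ...) {
  cat(sprintf(
    "<wingbeat_cycle> %s, %d points, %.1f Hz, Phi_sp %.1f deg, yaw %.1f deg\n",
    x$mode, x$n, x$wingbeat_freq_hz, x$stroke_amplitude_deg, x$yaw_deg))
  invisible(x)
}

#' Mirror a wingbeat cycle through the sagittal plane
#'
#' Swaps the left and right wings and negates the lateral components (yaw,
#' body velocity); used for reflection-symmetry checks and to construct an
#' exactly mirrored tracking condition.
#'
#' @param cyc A [wingbeat_cycle()].
#' @return The mirrored `wingbeat_cycle`.
#' @export
reflect_cycle <- function(cyc) {
  stopifnot(inherits(cyc, "wingbeat_cycle"))
  out <- cyc
  for (fld in c("phi", "elev", "alpha")) {
    out[[fld]] <- list(left = cyc[[fld]]$right, right = cyc[[fld]]$left)
  }
  out$v_body <- cyc$v_body * c(1, -1, 1)
  out$yaw_deg <- -cyc$yaw_deg
  out$mode <- switch(cyc$mode, left = "right", right = "left", cyc$mode)
  out
}
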