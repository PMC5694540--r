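#' Wing bank angle
#'
#' Half the difference between the left and right wings' average elevation
#' angles; positive when the left wing is elevated and the right depressed.
#'
#' @param left_elev_deg,right_elev_deg Mean elevation angles (degrees) for a
#'   stroke phase.
#' @return WBA in degrees.
#' @examples
#' compute_wba(4, -4)   # 4
#' @export
compute_wba <- function(left_elev_deg, right_elev_deg) {
  (left_elev_deg - right_elev_deg) / 2
}

#' Relative wing bank angle
#'
#' Wing bank relative to the frontal body axis: the absolute value of the
#' sum of the WBA and the frontal body angle. Zero when the wings are
#' perpendicular to the dorsoventral body axis.
#'
#' @param wba_deg Wing bank angle (degrees).
#' @param chi_yz_deg Frontal body angle (degrees, deviation from vertical,
#'   positive toward the bird's left).
#' @return RWBA in degrees (>= 0).
#' @examples
#' compute_rwba(4.0, 3.5)   # 7.5
#' @export
compute_rwba <- function(wba_deg, chi_yz_deg) {
  abs(wba_deg + chi_yz_deg)
}

# per-frame elevation angle (deg above horizontal) of shoulder -> wingtip
wing_elevation_deg <- function(lm, side) {
  tip <- lm$coords[[paste0(substr(side, 1L, 1L), "_wingtip")]]
  sh <- lm$coords[[paste0(substr(side, 1L, 1L), "_shoulder")]]
  rel <- tip - sh
  rad2deg(asin(clamp(rel[, 3L] / row_norms(rel), -1, 1)))
}

#' Body angles in the gravitational frame
#'
#' The lateral body angle (sagittal plane) is the elevation of the
#' tail-to-head axis above horizontal; the frontal body angle is the
#' deviation of the dorsoventral axis from vertical, positive when the body
#' tilts toward the bird's left (measured from the shoulder line).
#'
#' @param lm A head-aligned `landmark_set` (see [transform_frame()]).
#' @return Data frame with per-frame `chi_xz_deg` and `chi_yz_deg`.
#' @export
compute_body_angles <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  body <- lm$coords$head - lm$coords$tail
  if (any(row_norms(body) < 1e-9)) stopf("coincident head and tail positions")
  chi_xz <- rad2deg(atan2(body[, 3L], body[, 1L]))
  sh <- lm$coords$l_shoulder - lm$coords$r_shoulder
  chi_yz <- -rad2deg(atan2(sh[, 3L], sh[, 2L]))
  data.frame(chi_xz_deg = chi_xz, chi_yz_deg = chi_yz)
}

#' Travel angle
#'
#' Signed angle between the wingtip-path dividing line and the feeder axis
#' (+x), expressed relative to the direction of travel: positive when the
#' bird faces the direction of motion, negative when it faces away. Not
#' defined for hovering, where `NA` is returned.
#'
#' @param yaw_deg Yaw of the dividing line from +x toward +y (degrees).
#' @param mode `"hover"`, `"left"` or `"right"`.
#' @return Psi in degrees, or `NA_real_` for hovering.
#' @examples
#' compute_travel_angle(21.9, "left")    # 21.9
#' compute_travel_angle(10.3, "right")   # -10.3
#' @export
compute_travel_angle <- function(yaw_deg, mode = c("hover", "left", "right")) {
  mode <- match.arg(mode)
  s <- travel_sign(mode)
  if (is.na(s)) return(NA_real_)
  s * yaw_deg
}

#' Geometric angle of attack time course
#'
#' Angle between the wing plane -- defined by the shoulder, wingtip and tip
#' of the 5th primary -- and the horizontal, in `[0, 90]`: 0 means the wing
#' is horizontal, 90 vertical. Frames with collinear points are flagged and
#' linearly interpolated.
#'
#' @param shoulder,wingtip,p5 n-by-3 position matrices.
#' @return Numeric vector of per-frame angles (degrees).
#' @export
compute_geometric_alpha <- function(shoulder, wingtip, p5) {
  nvec <- cross3_rows(wingtip - shoulder, p5 - shoulder)
  nn <- row_norms(nvec)
  alpha <- rad2deg(acos(clamp(abs(nvec[, 3L]) / nn, 0, 1)))
  bad <- nn < 1e-12
  if (any(bad)) {
    if (all(bad)) stopf("all frames have collinear wing points")
    idx <- seq_along(alpha)
    alpha[bad] <- stats::approx(idx[!bad], alpha[!bad], xout = idx[bad],
                                rule = 2)$y
  }
  alpha
}

#' Bill insertion percentage
#'
#' The bill is modelled as a segment of length `culmen_length_m` along the
#' head's forward axis; the insertion is the percentage of that segment
#' lying beyond the feeder mouth plane (normal to +x at `feeder_mouth_x`),
#' clamped to `[0, 100]`.
#'
#' @param head n-by-3 head positions (raw, untransformed coordinates).
#' @param forward_axis Length-3 (or n-by-3) unit forward axis of the head.
#' @param feeder_mouth_x x-coordinate of the feeder mouth plane (m).
#' @param culmen_length_m Exposed culmen length (m), > 0.
#' @return Per-frame insertion percentages.
#' @export
compute_bill_insertion <- function(head, forward_axis, feeder_mouth_x,
                                   culmen_length_m) {
  if (culmen_length_m <= 0) stopf("culmen_length_m must be positive")
  if (is.null(dim(forward_axis))) {
    forward_axis <- matrix(forward_axis, nrow(head), 3L, byrow = TRUE)
  }
  tip_x <- head[, 1L] + culmen_length_m * forward_axis[, 1L]
  fx <- forward_axis[, 1L]
  fx[abs(fx) < 1e-9] <- 1e-9
  beyond <- (tip_x - feeder_mouth_x) / (culmen_length_m * fx)
  100 * clamp(beyond, 0, 1)
}

# masks and cycle bookkeeping -------------------------------------------------

# interior cycles: drop the first and last detected wingbeat to avoid filter
# and segmentation edge effects
interior_cycles <- function(seg, side = "left") {
  pron <- seg[[side]]$pronation_i
  k <- length(pron) - 1L
  if (k >= 4L) 2:(k - 1L) else seq_len(k)
}

phase_masks <- function(seg, side, cycle_k) {
  pron <- seg[[side]]$pronation_i
  i0 <- pron[cycle_k]; i1 <- pron[cycle_k + 1L]
  sup <- seg[[side]]$supination_i
  sup <- sup[sup > i0 & sup < i1]
  if (length(sup) == 0L) return(NULL)
  sup <- sup[1L]
  list(ds = i0:sup, us = (sup + 1L):i1, bounds = c(i0, sup, i1))
}

#' Summarize the kinematics of one trial
#'
#' Runs the full landmark pipeline: wingbeat-frequency estimation,
#' zero-phase Butterworth filtering, stroke segmentation, head-aligned
#' frame transform, and per-wingbeat computation of the kinematic
#' variables, averaged across interior wingbeats. Downstroke/upstroke
#' sample assignment uses the detected pronation-supination intervals of
#' the left wing for body variables and each wing's own intervals for its
#' elevation means.
#'
#' @param lm A raw `landmark_set`.
#' @param mode `"hover"`, `"left"` or `"right"`.
#' @param rwba_aggregation `"abs_of_mean"` (default; absolute value of the
#'   trial-mean WBA + chi sum) or `"mean_of_abs"` (per-wingbeat absolute
#'   values averaged).
#' @param feeder_mouth_x,culmen_length_m Feeder geometry for bill
#'   insertion; defaults come from the landmark set's attributes when
#'   present.
#' @return An object of class `kinematic_summary`: one-row data frame with
#'   `psi_deg`, `chi_xz_ds`, `chi_xz_us`, `chi_yz_ds`, `chi_yz_us`,
#'   `wba_ds`, `wba_us`, `rwba_ds`, `rwba_us`, `phi_sp_deg`,
#'   `wingbeat_freq_hz`, `bill_pct`, `n_wingbeats`; the per-wing geometric
#'   angle-of-attack traces are kept in the `"alpha"` attribute.
#' @export
summarize_trial <- function(lm, mode = c("hover", "left", "right"),
                            rwba_aggregation = c("abs_of_mean", "mean_of_abs"),
                            feeder_mouth_x = attr(lm, "feeder_mouth_x"),
                            culmen_length_m = attr(lm, "culmen_length_m")) {
  mode <- match.arg(mode)
  rwba_aggregation <- match.arg(rwba_aggregation)
  stopifnot(inherits(lm, "landmark_set"))
  f0 <- estimate_wingbeat_frequency(lm)
  flt <- filter_trajectories(lm, f0)
  seg <- segment_strokes(flt)
  tr <- transform_frame(flt, seg)
  yaw <- attr(tr, "yaw_deg")

  elev <- list(left = wing_elevation_deg(tr, "left"),
               right = wing_elevation_deg(tr, "right"))
  body <- compute_body_angles(tr)

  cycles <- interior_cycles(seg, "left")
  per <- lapply(cycles, function(k) {
    ml <- phase_masks(seg, "left", k)
    mr <- phase_masks(seg, "right", k)
    if (is.null(ml) || is.null(mr)) return(NULL)
    wba_ds <- compute_wba(mean(elev$left[ml$ds]), mean(elev$right[mr$ds]))
    wba_us <- compute_wba(mean(elev$left[ml$us]), mean(elev$right[mr$us]))
    # per-wingbeat stroke amplitude from a per-cycle stroke-plane fit
    amp <- vapply(c("left", "right"), function(side) {
      m <- if (side == "left") ml else mr
      idx <- m$bounds[1L]:m$bounds[3L]
      tipnm <- paste0(substr(side, 1L, 1L), "_wingtip")
      shnm <- paste0(substr(side, 1L, 1L), "_shoulder")
      rel <- tr$coords[[tipnm]][idx, ] - tr$coords[[shnm]][idx, ]
      sp <- stroke_plane_excursion(rel, c(1, 0, 0))
      diff(range(sp$angle))
    }, 0)
    data.frame(
      wba_ds = wba_ds, wba_us = wba_us,
      chi_xz_ds = mean(body$chi_xz_deg[ml$ds]),
      chi_xz_us = mean(body$chi_xz_deg[ml$us]),
      chi_yz_ds = mean(body$chi_yz_deg[ml$ds]),
      chi_yz_us = mean(body$chi_yz_deg[ml$us]),
      phi_sp_deg = mean(amp),
      yaw_deg = yaw[min(k, length(yaw))])
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) < 1L) stopf("no complete wingbeat cycles")

  mu <- colMeans(per)
  rwba <- function(wba, chi, wba_k, chi_k) {
    if (rwba_aggregation == "abs_of_mean") {
      compute_rwba(wba, chi)
    } else {
      mean(compute_rwba(wba_k, chi_k))
    }
  }

  bill <- NA_real_
  if (!is.null(feeder_mouth_x) && !is.null(culmen_length_m)) {
    eta <- deg2rad(mean(yaw))
    bill <- mean(compute_bill_insertion(lm$coords$head,
                                        c(cos(eta), sin(eta), 0),
                                        feeder_mouth_x, culmen_length_m))
  }

  out <- data.frame(
    mode = mode,
    psi_deg = compute_travel_angle(mean(yaw), mode),
    chi_xz_ds = mu[["chi_xz_ds"]], chi_xz_us = mu[["chi_xz_us"]],
    chi_yz_ds = mu[["chi_yz_ds"]], chi_yz_us = mu[["chi_yz_us"]],
    wba_ds = mu[["wba_ds"]], wba_us = mu[["wba_us"]],
    rwba_ds = rwba(mu[["wba_ds"]], mu[["chi_yz_ds"]],
                   per$wba_ds, per$chi_yz_ds),
    rwba_us = rwba(mu[["wba_us"]], mu[["chi_yz_us"]],
                   per$wba_us, per$chi_yz_us),
    phi_sp_deg = mu[["phi_sp_deg"]],
    wingbeat_freq_hz = seg$wingbeat_freq_hz,
    bill_pct = bill,
    n_wingbeats = nrow(per))
  attr(out, "per_wingbeat") <- per
  attr(out, "segmentation") <- seg
  class(out) <- c("kinematic_summary", "data.frame")
  out
}

#' Phase-normalized average wingbeat from landmark data
#'
#' Resamples every interior wingbeat of each wing onto a fixed phase grid
#' (`down_points` downstroke + the remainder upstroke samples, the 48:52
#' split by default) and averages across wingbeats, yielding the
#' [wingbeat_cycle()] structure consumed by the quasi-steady force model.
#' Body velocity is estimated from the raw head drift and the yaw from the
#' wingtip-path dividing line.
#'
#' @param lm A raw `landmark_set`.
#' @param mode Flight mode.
#' @param n_points Number of phase points (default 200).
#' @param downstroke_fraction Fraction of points labelled downstroke
#'   (default 0.48).
#' @return A `wingbeat_cycle`.
#' @export
average_wingbeat <- function(lm, mode = c("hover", "left", "right"),
                             n_points = 200L, downstroke_fraction = 0.48) {
  mode <- match.arg(mode)
  stopifnot(inherits(lm, "landmark_set"))
  n <- as.integer(n_points)
  n_ds <- as.integer(round(downstroke_fraction * n))
  f0 <- estimate_wingbeat_frequency(lm)
  flt <- filter_trajectories(lm, f0)
  seg <- segment_strokes(flt)
  tr <- transform_frame(flt, seg)

  alpha <- list(
    left = compute_geometric_alpha(tr$coords$l_shoulder, tr$coords$l_wingtip,
                                   tr$coords$l_p5),
    right = compute_geometric_alpha(tr$coords$r_shoulder, tr$coords$r_wingtip,
                                    tr$coords$r_p5))
  elev <- list(left = wing_elevation_deg(tr, "left"),
               right = wing_elevation_deg(tr, "right"))

  resamp <- function(x, idx, m) {
    if (length(idx) < 2L) return(rep(NA_real_, m))
    stats::approx(seq_along(idx), x[idx], xout = seq(1, length(idx),
                                                     length.out = m))$y
  }

  traces <- list()
  amps <- c()
  for (side in c("left", "right")) {
    cycles <- interior_cycles(seg, side)
    acc <- list(phi = 0, elev = 0, alpha = 0)
    cnt <- 0L
    for (k in cycles) {
      m <- phase_masks(seg, side, k)
      if (is.null(m)) next
      idx <- m$bounds[1L]:m$bounds[3L]
      tipnm <- paste0(substr(side, 1L, 1L), "_wingtip")
      shnm <- paste0(substr(side, 1L, 1L), "_shoulder")
      rel <- tr$coords[[tipnm]][idx, ] - tr$coords[[shnm]][idx, ]
      sp <- stroke_plane_excursion(rel, c(1, 0, 0))
      exc <- rep(NA_real_, length(elev[[side]]))
      exc[idx] <- sp$angle
      amps <- c(amps, diff(range(sp$angle)))
      ds <- m$ds; us <- m$us
      phi_k <- c(resamp(exc, ds, n_ds), resamp(exc, us, n - n_ds))
      elev_k <- c(resamp(elev[[side]], ds, n_ds),
                  resamp(elev[[side]], us, n - n_ds))
      alpha_k <- c(resamp(alpha[[side]], ds, n_ds),
                   resamp(alpha[[side]], us, n - n_ds))
      acc$phi <- acc$phi + phi_k
      acc$elev <- acc$elev + elev_k
      acc$alpha <- acc$alpha + alpha_k
      cnt <- cnt + 1L
    }
    if (cnt < 1L) stopf("no complete wingbeat cycles for the %s wing", side)
    traces[[side]] <- lapply(acc, function(a) a / cnt)
  }

  # body velocity from raw head drift
  vb <- vapply(1:3, function(j) {
    stats::coef(stats::lm.fit(cbind(1, lm$time_s), lm$coords$head[, j]))[2L]
  }, 0)

  ph <- (seq_len(n) - 1L) / n
  cyc <- list(
    n = n, phase = ph,
    stroke = factor(ifelse(ph < downstroke_fraction, "down", "up"),
                    levels = c("down", "up")),
    phi = list(left = traces$left$phi, right = traces$right$phi),
    elev = list(left = traces$left$elev, right = traces$right$elev),
    alpha = list(left = traces$left$alpha, right = traces$right$alpha),
    wingbeat_freq_hz = seg$wingbeat_freq_hz,
    downstroke_fraction = downstroke_fraction,
    stroke_amplitude_deg = mean(amps),
    v_body = as.numeric(vb),
    yaw_deg = mean(attr(tr, "yaw_deg")),
    mode = mode)
  class(cyc) <- "wingbeat_cycle"
  validate_cycle(cyc)
}
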