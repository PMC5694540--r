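#' Synthetic 3D landmark trajectories
#'
#' Generates the eight digitized anatomical landmarks (head, tail, left and
#' right shoulder, wingtip and 5th-primary tip) at 1,000 frames/s for a
#' hovering or feeder-tracking trial. Wingtip motion follows the parametric
#' stroke waveforms of [wing_waveforms()]; the body is pitched, rolled and
#' yawed per the mode's body angles and travel angle; the whole bird
#' translates laterally at the feeder speed in tracking modes; Gaussian
#' positional noise emulates digitization error.
#'
#' Axes: x = forward along the feeder axis, y = lateral (positive toward
#' the bird's left), z = vertical up. The feeder mouth plane is normal to x.
#'
#' @param params A [kinematic_sim_params()] object.
#' @param frame_rate Frames per second (default 1000).
#' @return A `landmark_set` (see [landmark_set()]) with attributes
#'   `feeder_mouth_x` and `culmen_length_m` describing the feeder geometry.
#' @examples
#' lm <- simulate_landmarks(kinematic_sim_params("hover", n_wingbeats = 6))
#' @export
simulate_landmarks <- function(params, frame_rate = 1000) {
  stopifnot(inherits(params, "kinematic_sim_params"))
  p <- params
  wf <- wing_waveforms(p)
  f <- p$wingbeat_freq
  t <- seq(0, p$n_wingbeats / f, by = 1 / frame_rate)
  nt <- length(t)
  ph <- (t * f) %% 1

  eta <- deg2rad(body_yaw_deg(p))
  s <- travel_sign(p$mode)
  v_lat <- if (is.na(s)) 0 else s * p$feeder_speed_m_s

  body_len <- 0.09
  shoulder_back <- 0.02
  shoulder_half <- 0.012
  wing_len <- 0.0525
  p5_span <- 0.65
  chord_len <- 0.013
  feeder_mouth_x <- 0.05

  fwd <- c(cos(eta), sin(eta), 0)            # horizontal head-forward axis
  # head placed so the bill tip lies bill_insertion_pct beyond the mouth plane
  head0_x <- feeder_mouth_x -
    p$culmen_length_m * cos(eta) * (1 - p$bill_insertion_pct / 100)
  head0 <- c(head0_x, 0, 0.25)

  chi_xz <- deg2rad(wf$chi_xz(ph))
  chi_yz <- deg2rad(wf$chi_yz(ph))

  # body axis (tail -> head): pitched up chi_xz, rolled about the forward
  # axis so the dorsoventral axis deviates chi_yz toward the bird's left,
  # then yawed by eta
  ax_b <- cos(chi_xz)
  ay_b <- sin(chi_xz) * sin(chi_yz)
  az_b <- sin(chi_xz) * cos(chi_yz)
  body_axis <- cbind(cos(eta) * ax_b - sin(eta) * ay_b,
                     sin(eta) * ax_b + cos(eta) * ay_b,
                     az_b)
  # body lateral axis (toward the bird's left), rolled with the body
  ly_b <- cos(chi_yz)
  lz_b <- -sin(chi_yz)
  lat_axis <- cbind(-sin(eta) * ly_b, cos(eta) * ly_b, lz_b)

  head <- cbind(head0[1L], head0[2L] + v_lat * t, head0[3L])
  tail <- head - body_len * body_axis
  sh_base <- head - shoulder_back * body_axis
  l_shoulder <- sh_base + shoulder_half * lat_axis
  r_shoulder <- sh_base - shoulder_half * lat_axis

  wing_points <- function(side) {
    sigma <- if (side == "left") 1 else -1
    phi <- deg2rad(wf$excursion(ph))
    e <- deg2rad(wf$elev[[side]](ph))
    alpha <- deg2rad(wf$alpha[[side]](ph))
    # spanwise unit vector in the bird frame, then yawed
    hx <- sin(phi); hy <- sigma * cos(phi)
    u <- cbind(cos(e) * (cos(eta) * hx - sin(eta) * hy),
               cos(e) * (sin(eta) * hx + cos(eta) * hy),
               sin(e))
    sh <- if (side == "left") l_shoulder else r_shoulder
    tip <- sh + wing_len * u
    # wing-plane chord direction: rotate the horizontal in-plane vector `a`
    # (oriented backward relative to wing motion) by alpha about the span
    bvec <- unit_rows(cbind(-u[, 3L] * u[, 1L], -u[, 3L] * u[, 2L],
                            1 - u[, 3L]^2))
    avec <- cross3_rows(bvec, u)
    # horizontal sweep direction (sign of dphi/dt times tangent)
    tx <- cos(phi); ty <- -sigma * sin(phi)
    sweep <- wf$sweep_sign(ph)
    mot <- cbind((cos(eta) * tx - sin(eta) * ty) * sweep,
                 (sin(eta) * tx + cos(eta) * ty) * sweep, 0)
    flip <- sign(rowSums(avec * mot))
    flip[flip == 0] <- 1
    avec <- -avec * flip
    chord <- cos(alpha) * avec - sin(alpha) * bvec
    p5 <- sh + p5_span * wing_len * u + chord_len * chord
    list(tip = tip, p5 = p5)
  }

  lw <- wing_points("left")
  rw <- wing_points("right")

  coords <- list(head = head, tail = tail,
                 l_shoulder = l_shoulder, r_shoulder = r_shoulder,
                 l_wingtip = lw$tip, r_wingtip = rw$tip,
                 l_p5 = lw$p5, r_p5 = rw$p5)

  with_seed(p$seed, {
    if (p$noise_sd_m > 0) {
      coords <- lapply(coords, function(m) {
        m + matrix(stats::rnorm(length(m), sd = p$noise_sd_m), nt, 3L)
      })
    }
    out <- new_landmark_set(t, coords)
    attr(out, "feeder_mouth_x") <- feeder_mouth_x
    attr(out, "culmen_length_m") <- p$culmen_length_m
    attr(out, "mode") <- p$mode
    out
  })
}
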