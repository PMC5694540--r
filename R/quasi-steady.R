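#' Wing morphology and physical constants
#'
#' Species-averaged values for Anna's hummingbird used by the quasi-steady
#' model: wing area, wing length, non-dimensional radius of the second
#' moment of wing area, body mass, air density and gravitational
#' acceleration.
#'
#' @param S Wing surface area (m^2), default 6.78e-4.
#' @param L Wing length (m), default 0.0525.
#' @param r2 Non-dimensional second-moment radius, default 0.499.
#' @param M Body mass (kg), default 0.00468.
#' @param rho Air density (kg/m^3), default 1.18.
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @return A list of class `wing_morphology`.
#' @export
wing_morphology <- function(S = 6.78e-4, L = 0.0525, r2 = 0.499,
                            M = 0.00468, rho = 1.18, g = 9.81) {
  vals <- c(S = S, L = L, r2 = r2, M = M, rho = rho, g = g)
  if (any(vals <= 0)) stopf("all morphology constants must be positive")
  if (r2 > 1) stopf("r2 must be <= 1")
  structure(as.list(vals), class = "wing_morphology")
}

#' Empirical lift and drag coefficient curve constants
#'
#' The sixteen constants of the four cosine curves (offset, amplitude,
#' per-degree frequency, radian phase) fitted to revolving Anna's
#' hummingbird wings, one lift and one drag curve per stroke phase. The
#' per-degree frequency constants multiply the angle of attack in degrees;
#' the result plus the radian phase offset is evaluated with a radian
#' cosine. Upstroke curves are parameterized in `alpha_aero - 180`.
#'
#' @param cl_down,cd_down,cl_up,cd_up Length-4 numeric vectors
#'   `c(offset, amplitude, freq_per_deg, phase_rad)`.
#' @return A list of class `aero_coefficients`.
#' @export
aero_coefficients <- function(cl_down = c(0.0031, 1.5842, 0.0301, 4.7124),
                              cd_down = c(8.3171, 8.1909, 0.0073, 3.1416),
                              cl_up = c(0.0028, 1.1251, 0.0332, 4.6963),
                              cd_up = c(1.1993, 1.0938, 0.0281, 3.1277)) {
  for (v in list(cl_down, cd_down, cl_up, cd_up)) {
    stopifnot(length(v) == 4L)
    if (v[2L] < 0) stopf("coefficient-curve amplitudes must be >= 0")
  }
  structure(list(cl_down = cl_down, cd_down = cd_down,
                 cl_up = cl_up, cd_up = cd_up),
            class = "aero_coefficients")
}

eval_curve <- function(cf, alpha_deg) {
  cf[1L] + cf[2L] * cos(cf[3L] * alpha_deg + cf[4L])
}

#' Lift and drag coefficients at an aerodynamic angle of attack
#'
#' Evaluates the empirical cosine curves. `alpha_aero_deg` follows the
#' stroke-phase sign convention: downstroke angles are fed directly;
#' upstroke angles are measured on a 180-degree-offset scale, so an
#' upstroke wing meeting the flow at `beta` degrees is evaluated at
#' `180 + beta`.
#'
#' @param alpha_aero_deg Aerodynamic angle of attack (degrees).
#' @param stroke_phase `"down"` or `"up"` (vectorized).
#' @param coefficients An [aero_coefficients()] object.
#' @return List with numeric vectors `CL` and `CD`.
#' @examples
#' lift_drag_coefficients(0, "down")   # CL ~ 0.0031, CD ~ 0.126
#' @export
lift_drag_coefficients <- function(alpha_aero_deg, stroke_phase,
                                   coefficients = aero_coefficients()) {
  up <- stroke_phase == "up"
  n <- max(length(alpha_aero_deg), length(up))
  alpha <- rep_len(alpha_aero_deg, n)
  up <- rep_len(up, n)
  CL <- ifelse(up, eval_curve(coefficients$cl_up, alpha - 180),
               eval_curve(coefficients$cl_down, alpha))
  CD <- ifelse(up, eval_curve(coefficients$cd_up, alpha - 180),
               eval_curve(coefficients$cd_down, alpha))
  list(CL = CL, CD = CD)
}

#' Radius of gyration of the wing
#'
#' @param r2 Non-dimensional second-moment radius (0 < r2 <= 1).
#' @param L Wing length (m), > 0.
#' @return `r2 * L` in meters.
#' @export
radius_of_gyration <- function(r2, L) {
  if (r2 <= 0 || r2 > 1) stopf("r2 must be in (0, 1]")
  if (L <= 0) stopf("L must be positive")
  r2 * L
}

#' Actuator disk area swept by the wings
#'
#' `A_disk = (Phi_sp / 180) * pi * L^2`, with the stroke amplitude in
#' degrees.
#'
#' @param phi_sp_deg Stroke amplitude (degrees, 0 < Phi_sp <= 360).
#' @param L Wing length (m).
#' @return Disk area (m^2).
#' @export
actuator_disk_area <- function(phi_sp_deg, L) {
  if (phi_sp_deg <= 0 || phi_sp_deg > 360) stopf("phi_sp_deg must be in (0, 360]")
  if (L <= 0) stopf("L must be positive")
  (phi_sp_deg / 180) * pi * L^2
}

#' Rankine-Froude induced velocity (hovering)
#'
#' Momentum-theory downwash for hovering: `sqrt(M g / (2 rho A_disk))`,
#' applied as a uniform downward air velocity. The hovering form is used
#' for all flight modes here because the lateral flight speeds are well
#' below 1 m/s.
#'
#' @param M Body mass (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @param rho Air density (kg/m^3).
#' @param A_disk Actuator disk area (m^2), > 0.
#' @return Induced velocity (m/s).
#' @export
induced_velocity <- function(M, g, rho, A_disk) {
  if (A_disk <= 0) stopf("A_disk must be positive")
  if (M <= 0 || g <= 0 || rho <= 0) stopf("M, g and rho must be positive")
  sqrt(M * g / (2 * rho * A_disk))
}

#' Incident velocity at the blade element
#'
#' Relative wind seen by the wing: the reversed wing velocity at the radius
#' of gyration, plus the downward induced velocity, plus the reversed body
#' velocity (air moves opposite to the bird).
#'
#' @param wing_velocity n-by-3 wing velocity at R_gyr (m/s).
#' @param v_induced Induced-velocity magnitude (m/s, downward).
#' @param v_body Length-3 body velocity (m/s).
#' @return n-by-3 incident velocity matrix.
#' @export
incident_velocity <- function(wing_velocity, v_induced, v_body = c(0, 0, 0)) {
  -wing_velocity +
    matrix(c(-v_body[1L], -v_body[2L], -v_body[3L] - v_induced),
           nrow(wing_velocity), 3L, byrow = TRUE)
}

# geometry of one wing over the cycle, in the bird (dividing-line) frame
wing_vectors <- function(cyc, side, Rgyr) {
  sigma <- if (side == "left") 1 else -1
  phi <- deg2rad(cyc$phi[[side]])
  e <- deg2rad(cyc$elev[[side]])
  u <- cbind(cos(e) * sin(phi), sigma * cos(e) * cos(phi), sin(e))
  dt <- 1 / (cyc$wingbeat_freq_hz * cyc$n)
  pos <- Rgyr * u
  vel <- apply(pos, 2L, periodic_gradient, dt = dt)
  list(u = u, vel = vel, sigma = sigma)
}

#' Instantaneous quasi-steady forces over the wingbeat
#'
#' Blade-element evaluation at the radius of gyration, carrying the full
#' wing area: at each of the cycle's equally spaced time points the lift is
#' `1/2 CL rho S |V_incident|^2` perpendicular to the incident flow (along
#' the unit cross product of the leading-edge vector, shoulder to wingtip,
#' with `V_incident`, flipped if needed so its vertical component is
#' positive) and the drag is `1/2 CD rho S |V_incident|^2` along
#' `V_incident`. The aerodynamic angle of attack is the angle between the
#' wing plane and the local incident flow, signed by stroke phase for the
#' coefficient lookup. Forces are expressed in body weights in the
#' bird-centered frame (x forward, y toward the bird's left, z up); body
#' velocity is rotated into that frame from global coordinates.
#'
#' @param cyc A [wingbeat_cycle()].
#' @param morphology A [wing_morphology()].
#' @param coefficients An [aero_coefficients()].
#' @param v_induced Optional induced-velocity override (m/s); by default it
#'   is computed from the morphology and the cycle's stroke amplitude.
#' @return An object of class `force_time_series`: list with `phase`,
#'   `stroke`, per-wing `lift`, `drag`, `total` (n-by-3 matrices, wb), `cl`,
#'   `cd`, `alpha_aero`, `v_incident`, and `net` (n-by-3, wb), plus cycle
#'   metadata.
#' @export
instantaneous_forces <- function(cyc, morphology = wing_morphology(),
                                 coefficients = aero_coefficients(),
                                 v_induced = NULL) {
  stopifnot(inherits(cyc, "wingbeat_cycle"))
  mo <- morphology
  Rgyr <- radius_of_gyration(mo$r2, mo$L)
  Vi <- if (is.null(v_induced)) {
    induced_velocity(mo$M, mo$g, mo$rho,
                     actuator_disk_area(cyc$stroke_amplitude_deg, mo$L))
  } else {
    v_induced
  }
  # body velocity in the bird frame
  vb <- as.numeric(rot_z(-deg2rad(cyc$yaw_deg)) %*% cyc$v_body)
  up <- cyc$stroke == "up"
  weight <- mo$M * mo$g

  per_wing <- function(side) {
    wv <- wing_vectors(cyc, side, Rgyr)
    u <- wv$u
    Vinc <- incident_velocity(wv$vel, Vi, vb)
    Vmag <- row_norms(Vinc)
    ok <- Vmag > 1e-12
    Vhat <- Vinc
    Vhat[ok, ] <- Vinc[ok, ] / Vmag[ok]
    Vhat[!ok, ] <- 0

    # wing-plane normal from the spanwise axis and the alpha-rotated chord
    alpha <- deg2rad(cyc$alpha[[side]])
    bvec <- unit_rows(cbind(-u[, 3L] * u[, 1L], -u[, 3L] * u[, 2L],
                            1 - u[, 3L]^2))
    avec <- cross3_rows(bvec, u)
    flip <- sign(rowSums(avec * wv$vel))
    flip[flip == 0] <- 1
    avec <- -avec * flip
    chord <- cos(alpha) * avec - sin(alpha) * bvec
    nvec <- unit_rows(cross3_rows(u, chord))

    beta <- rad2deg(asin(clamp(abs(rowSums(nvec * Vhat)), 0, 1)))
    alpha_aero <- ifelse(up, 180 + beta, beta)
    cc <- lift_drag_coefficients(alpha_aero, cyc$stroke, coefficients)

    q <- 0.5 * mo$rho * mo$S * Vmag^2
    lraw <- cross3_rows(u, Vinc)
    lnorm <- row_norms(lraw)
    lok <- lnorm > 1e-12 & ok
    lhat <- lraw
    lhat[lok, ] <- lraw[lok, ] / lnorm[lok]
    lhat[!lok, ] <- 0
    zsign <- sign(lhat[, 3L])
    zsign[zsign == 0] <- 1
    lhat <- lhat * zsign

    lift <- (q * cc$CL) * lhat / weight
    drag <- (q * cc$CD) * Vhat / weight
    list(lift = lift, drag = drag, total = lift + drag,
         cl = cc$CL, cd = cc$CD,
         alpha_aero = alpha_aero, v_incident = Vinc)
  }

  lw <- per_wing("left")
  rw <- per_wing("right")
  structure(list(
    phase = cyc$phase, stroke = cyc$stroke,
    left = lw, right = rw,
    net = lw$total + rw$total,
    wingbeat_freq_hz = cyc$wingbeat_freq_hz,
    v_induced = Vi, yaw_deg = cyc$yaw_deg, v_body = cyc$v_body,
    mode = cyc$mode), class = "force_time_series")
}

#' @export
print.force_time_series <- function(x, ...) {
  nf <- colMeans(x$net)
  cat(sprintf(paste0("<force_time_series> %s, %d points; net forward %.3f,",
                     " lateral %.3f, vertical %.3f wb\n"),
              x$mode, length(x$phase), nf[1L], nf[2L], nf[3L]))
  invisible(x)
}

#' Cycle-averaged net forces
#'
#' Time-averaged net forces per axis in body weights (the cycle points are
#' equally spaced in time, so the average is unweighted), plus the
#' projection of the mean horizontal force onto the travel direction for
#' tracking modes.
#'
#' @param fts A [instantaneous_forces()] result.
#' @param psi_deg Travel angle (degrees); defaults to the cycle's stored
#'   yaw/mode. Ignored for hovering.
#' @return List with `vertical_wb`, `forward_wb`, `lateral_wb`,
#'   `travel_wb` (`NA` for hovering) and `psi_deg`.
#' @export
net_forces <- function(fts, psi_deg = NULL) {
  stopifnot(inherits(fts, "force_time_series"))
  nf <- colMeans(fts$net)
  s <- travel_sign(fts$mode)
  psi <- if (!is.null(psi_deg)) psi_deg else {
    if (is.na(s)) NA_real_ else s * fts$yaw_deg
  }
  travel <- NA_real_
  if (!is.na(s)) {
    # travel direction (global +/-y) expressed in the bird frame
    tdir <- as.numeric(rot_z(-deg2rad(fts$yaw_deg)) %*% c(0, s, 0))
    travel <- sum(nf * tdir)
  }
  list(vertical_wb = nf[[3L]], forward_wb = nf[[1L]], lateral_wb = nf[[2L]],
       travel_wb = travel, psi_deg = psi)
}
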