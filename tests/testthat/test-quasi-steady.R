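test_that("radius of gyration, disk area and induced velocity close forms", {
  expect_equal(radius_of_gyration(0.499, 0.0525), 0.0261975)
  expect_equal(radius_of_gyration(1, 0.0525), 0.0525)
  expect_error(radius_of_gyration(0.499, 0), "positive")
  expect_error(radius_of_gyration(1.2, 0.05), "r2")

  L <- 0.0525
  expect_equal(actuator_disk_area(180, L), pi * L^2)
  expect_equal(actuator_disk_area(90, L), actuator_disk_area(180, L) / 2)
  expect_lt(actuator_disk_area(1e-4, L), 1e-8)
  expect_error(actuator_disk_area(0, L), "phi_sp")

  vi <- induced_velocity(0.00468, 9.81, 1.18, actuator_disk_area(180, L))
  expect_equal(vi, sqrt(0.00468 * 9.81 / (2 * 1.18 * pi * L^2)))
  expect_equal(round(vi, 3), 1.499)
  expect_equal(induced_velocity(4 * 0.00468, 9.81, 1.18, pi * L^2), 2 * vi)
  expect_lt(induced_velocity(0.00468, 9.81, 1.18, 1e6), 1e-3)
  expect_error(induced_velocity(0.00468, 9.81, 1.18, 0), "positive")
})

test_that("coefficient curves reproduce the empirical cosine fits", {
  # independent hand evaluation of the empirical cosine fits
  d0 <- lift_drag_coefficients(0, "down")
  expect_equal(d0$CL, 0.0031 + 1.5842 * cos(4.7124))
  expect_equal(d0$CL, 0.0031, tolerance = 0.05)
  expect_equal(d0$CD, 8.3171 + 8.1909 * cos(3.1416))
  expect_equal(d0$CD, 0.1262, tolerance = 1e-3)

  # lift maximum where the cosine argument reaches 2*pi: alpha ~ 52.2 deg
  amax <- (2 * pi - 4.7124) / 0.0301
  expect_equal(amax, 52.2, tolerance = 0.01)
  expect_equal(lift_drag_coefficients(amax, "down")$CL, 0.0031 + 1.5842,
               tolerance = 1e-6)

  u180 <- lift_drag_coefficients(180, "up")
  expect_equal(u180$CL, 0.0028 + 1.1251 * cos(4.6963))
  expect_equal(u180$CL, 0, tolerance = 0.02)

  # monotone drag over [0, 90]; lift rises to the ~52 deg peak then falls
  alphas <- seq(0, 90, by = 1)
  cds <- lift_drag_coefficients(alphas, "down")$CD
  expect_true(all(diff(cds) > 0))
  cls <- lift_drag_coefficients(alphas, "down")$CL
  expect_true(all(diff(cls[alphas < 50]) > 0))
  expect_true(all(diff(cls[alphas > 55]) < 0))
  peak <- alphas[which.max(cls)]
  expect_equal(peak, 52, tolerance = 1.5 / 52)
})

test_that("incident velocity composes wing, downwash and body terms", {
  still <- matrix(0, 5, 3L)
  expect_equal(incident_velocity(still, 0), still)
  vi1 <- incident_velocity(still, 1.2)
  expect_equal(vi1[, 3L], rep(-1.2, 5))
  # body motion shifts every incident vector by its negation
  vb <- incident_velocity(still, 1.2, c(0, 0.15, 0))
  expect_equal(vb[, 2L] - vi1[, 2L], rep(-0.15, 5))

  # |V_Rgyr| equals omega * R_gyr at mid-downstroke (finite-difference vs
  # analytic peak angular speed of the excursion waveform)
  par <- kinematic_sim_params("hover", wba_ds = 0, wba_us = 0)
  cyc <- wingbeat_cycle(par, 4000)
  mo <- wing_morphology()
  Rgyr <- radius_of_gyration(mo$r2, mo$L)
  dt <- 1 / (cyc$wingbeat_freq_hz * cyc$n)
  phi <- cyc$phi$left * pi / 180
  elev <- cyc$elev$left * pi / 180
  u <- cbind(cos(elev) * sin(phi), cos(elev) * cos(phi), sin(elev))
  vel <- apply(Rgyr * u, 2L, function(x) {
    n <- length(x); (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / (2 * dt)
  })
  speed_mid_ds <- sqrt(sum(vel[round(0.24 * cyc$n), ]^2))
  omega_peak <- (pi * (150 / 2) * pi / 180) / (0.48 / cyc$wingbeat_freq_hz)
  expect_equal(speed_mid_ds, omega_peak * Rgyr, tolerance = 0.01)
})

test_that("lift is perpendicular and drag parallel to the incident flow", {
  for (mode in c("hover", "left")) {
    fts <- instantaneous_forces(wingbeat_cycle(kinematic_sim_params(mode)))
    for (w in c("left", "right")) {
      lift <- fts[[w]]$lift
      drag <- fts[[w]]$drag
      v <- fts[[w]]$v_incident
      vn <- sqrt(rowSums(v^2))
      ln <- sqrt(rowSums(lift^2))
      cosld <- abs(rowSums(lift * v)) / (ln * vn + 1e-300)
      expect_lt(max(cosld), 1e-10)
      dn <- sqrt(rowSums(drag^2))
      cosdd <- rowSums(drag * v) / (dn * vn + 1e-300)
      expect_equal(min(cosdd), 1, tolerance = 1e-10)
      expect_equal(fts[[w]]$total, lift + drag)
      # the lift axis points upward by convention (a negative coefficient
      # then gives a downward force along that axis)
      expect_true(all(sign(fts[[w]]$cl) * lift[, 3L] >= -1e-12 | ln < 1e-12))
    }
  }
})

test_that("symmetric hovering produces mirrored wing forces, zero net lateral", {
  par <- kinematic_sim_params("hover", wba_ds = 0, wba_us = 0,
                              chi_yz_ds = 0, chi_yz_us = 0)
  fts <- instantaneous_forces(wingbeat_cycle(par))
  expect_equal(fts$left$total[, 2L], -fts$right$total[, 2L], tolerance = 1e-10)
  expect_equal(fts$left$total[, c(1L, 3L)], fts$right$total[, c(1L, 3L)],
               tolerance = 1e-10)
  expect_lt(abs(net_forces(fts)$lateral_wb), 1e-10)
})

test_that("forces scale linearly with density, area, and squared speed", {
  cyc <- wingbeat_cycle(kinematic_sim_params("left"))
  vi <- induced_velocity(0.00468, 9.81, 1.18, actuator_disk_area(150, 0.0525))
  f1 <- instantaneous_forces(cyc, wing_morphology(), v_induced = vi)
  # density enters the dynamic pressure linearly (at fixed incident flow;
  # the Rankine-Froude downwash is held at its reference value)
  f2 <- instantaneous_forces(cyc, wing_morphology(rho = 2 * 1.18),
                             v_induced = vi)
  expect_equal(f2$net, 2 * f1$net, tolerance = 1e-12)
  f3 <- instantaneous_forces(cyc, wing_morphology(S = 2 * 6.78e-4),
                             v_induced = vi)
  expect_equal(f3$net, 2 * f1$net, tolerance = 1e-12)
  # dynamic pressure is quadratic in incident speed: scaling the wingbeat
  # frequency (all velocities) by k scales dimensional forces by ~k^2
  k <- 1.5
  p2 <- kinematic_sim_params("hover", wba_ds = 0, wba_us = 0,
                             feeder_speed_m_s = 0)
  c1 <- wingbeat_cycle(p2)
  c2 <- wingbeat_cycle(kinematic_sim_params(
    "hover", wingbeat_freq = 39 * k, wba_ds = 0, wba_us = 0))
  g1 <- instantaneous_forces(c1, v_induced = 0)
  g2 <- instantaneous_forces(c2, v_induced = 0)
  expect_equal(g2$net, k^2 * g1$net, tolerance = 1e-9)
})

test_that("sagittal reflection negates lateral forces only", {
  cyc <- wingbeat_cycle(kinematic_sim_params("left"))
  f <- net_forces(instantaneous_forces(cyc))
  fm <- net_forces(instantaneous_forces(reflect_cycle(cyc)))
  expect_equal(fm$lateral_wb, -f$lateral_wb, tolerance = 1e-12)
  expect_equal(fm$vertical_wb, f$vertical_wb, tolerance = 1e-12)
  expect_equal(fm$forward_wb, f$forward_wb, tolerance = 1e-12)
})

test_that("net forces average instantaneous forces and project on travel", {
  cyc <- wingbeat_cycle(kinematic_sim_params("hover"))
  fts <- instantaneous_forces(cyc)
  # constant unit vertical force -> mean vertical exactly 1
  fts$net <- matrix(rep(c(0, 0, 1), each = cyc$n), cyc$n, 3L)
  expect_equal(net_forces(fts)$vertical_wb, 1)
  # zero-mean sinusoidal lateral force -> mean lateral 0
  fts$net[, 2L] <- sin(2 * pi * seq_len(cyc$n) / cyc$n)
  expect_equal(net_forces(fts)$lateral_wb, 0, tolerance = 1e-12)

  # tracking: net lateral force opposes the travel direction
  for (mode in c("left", "right")) {
    nf <- net_forces(instantaneous_forces(
      wingbeat_cycle(kinematic_sim_params(mode))))
    s <- if (mode == "left") 1 else -1
    expect_lt(s * nf$lateral_wb, 0)
    expect_lt(nf$travel_wb, 0)
  }
})

test_that("a zero-length incident velocity yields zero force, not NaN", {
  par <- kinematic_sim_params("hover", stroke_amplitude_deg = 1e-3,
                              wba_ds = 0, wba_us = 0)
  cyc <- wingbeat_cycle(par)
  # kill the downwash by making the disk huge via morphology density
  fts <- instantaneous_forces(cyc, wing_morphology(M = 1e-12))
  expect_true(all(is.finite(fts$net)))
})

test_that("model configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_model_config(path, wing_morphology(rho = 1.2),
                     aero_coefficients())
  cfg <- read_model_config(path)
  expect_equal(cfg$morphology$rho, 1.2)
  expect_equal(cfg$coefficients$cl_down, c(0.0031, 1.5842, 0.0301, 4.7124))
})
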