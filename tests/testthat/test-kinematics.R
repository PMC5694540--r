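test_that("Butterworth filtering is zero-phase with the per-landmark cutoffs", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  f0 <- 39
  lowband <- sin(2 * pi * f0 * t)
  high <- 0.5 * sin(2 * pi * 200 * t)
  mk <- function(head_x) {
    df <- do.call(rbind, lapply(
      c("head", "tail", "l_shoulder", "r_shoulder",
        "l_wingtip", "r_wingtip", "l_p5", "r_p5"),
      function(lm) data.frame(time_s = t, landmark = lm, x_m = head_x,
                              y_m = 0, z_m = 0.1)))
    landmark_set(df)
  }
  # DC-constant trajectories are unchanged
  lm_const <- mk(0.25)
  out <- filter_trajectories(lm_const, f0)
  expect_equal(out$coords$head[, 1L], rep(0.25, length(t)), tolerance = 1e-9)

  # head cutoff 2*f: 39 Hz passes within 5%... the head is filtered at 2f,
  # so test the wingtip channel (cutoff 8f = 312 Hz): passband gain ~1 and
  # 200 Hz < cutoff passes; use the tail (6f = 234 Hz) to check attenuation
  lm_mix <- mk(lowband + high)
  flt <- filter_trajectories(lm_mix, f0)
  interior <- 200:800
  # head channel (cutoff 78 Hz): 200 Hz removed > 40 dB, 39 Hz gain 1 +/- 5%
  resid <- flt$coords$head[interior, 1L]
  hi_gain <- sqrt(mean((resid - lowband[interior])^2) / mean(high^2))
  expect_lt(20 * log10(hi_gain + 1e-12), -40)
  lo_gain <- sqrt(mean(resid^2) / mean(lowband[interior]^2))
  expect_equal(lo_gain, 1, tolerance = 0.05)

  # zero phase: cross-correlation of raw and filtered band-limited signal
  # peaks at lag 0
  cc <- stats::ccf(lowband[interior], resid, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # filtering twice changes a band-limited signal only marginally
  flt2 <- filter_trajectories(flt, f0)
  expect_equal(flt2$coords$head[interior, 1L], flt$coords$head[interior, 1L],
               tolerance = 0.01)

  expect_error(filter_trajectories(lm_const, 70), "Nyquist")
})

test_that("stroke segmentation recovers frequency and transition times", {
  lm <- simulate_landmarks(kinematic_sim_params("hover", noise_sd_m = 0,
                                                n_wingbeats = 10L))
  seg <- segment_strokes(filter_trajectories(lm, 39))
  expect_equal(seg$wingbeat_freq_hz, 39, tolerance = 0.5 / 39)
  # pronations of the noise-free waveform fall at multiples of the period
  pron <- seg$left$pronation_t[2:4]
  cycles <- pron * 39
  expect_equal(cycles, round(cycles), tolerance = 0.02 / max(cycles))

  # noise at ~10% of the wing chord scale moves transitions < 1 ms
  lmn <- simulate_landmarks(kinematic_sim_params("hover", noise_sd_m = 1e-3,
                                                 n_wingbeats = 10L, seed = 2))
  segn <- segment_strokes(filter_trajectories(lmn, 39))
  k <- min(length(pron <- seg$left$pronation_t),
           length(pron_n <- segn$left$pronation_t))
  expect_lt(max(abs(pron[2:k] - pron_n[2:k])), 1e-3)

  short <- simulate_landmarks(kinematic_sim_params("hover", n_wingbeats = 1L))
  expect_error(segment_strokes(filter_trajectories(short, 39)), "cycles")
})

test_that("frame transform is translation invariant and recovers yaw", {
  par <- kinematic_sim_params("left", n_wingbeats = 10L, seed = 6)
  lm <- simulate_landmarks(par)
  s1 <- summarize_trial(lm, "left")
  s2 <- summarize_trial(translate_landmarks(lm, c(0.3, -0.2, 0.15)), "left",
                        feeder_mouth_x = NULL, culmen_length_m = NULL)
  for (v in c("wba_ds", "wba_us", "chi_xz_ds", "chi_yz_ds", "psi_deg")) {
    expect_equal(s2[[v]], s1[[v]], tolerance = 1e-6)
  }
  # dividing line recovers the generator yaw (travel angle 21.9 deg)
  expect_equal(s1$psi_deg, 21.9, tolerance = 1 / 21.9)

  # hovering: transform is identity up to tolerance (yaw ~ 0)
  lmh <- simulate_landmarks(kinematic_sim_params("hover", noise_sd_m = 0,
                                                 n_wingbeats = 8L))
  flt <- filter_trajectories(lmh, 39)
  seg <- segment_strokes(flt)
  tr <- transform_frame(flt, seg)
  expect_lt(max(abs(attr(tr, "yaw_deg"))), 0.5)
  expect_true(all(abs(tr$coords$head) < 1e-9))
})

test_that("wing bank angle conventions match the definitions", {
  expect_equal(compute_wba(4, -4), 4)
  expect_equal(compute_wba(2.7, 2.7), 0)
  expect_equal(compute_wba(-7.4, 7.4), -7.4)

  expect_equal(compute_rwba(4.0, 3.5), 7.5)
  expect_equal(compute_rwba(-7.4, -1.3), 8.7)
  expect_equal(compute_rwba(12.3, -12.3), 0)
})

test_that("body angles read pitch and frontal tilt from the landmarks", {
  n <- 50
  mkset <- function(head, tail, lsh, rsh) {
    coords <- list(head = head, tail = tail, l_shoulder = lsh,
                   r_shoulder = rsh)
    for (nm in c("l_wingtip", "r_wingtip", "l_p5", "r_p5")) {
      coords[[nm]] <- matrix(c(0, 0, 0), n, 3L, byrow = TRUE)
    }
    structure(list(time_s = seq_len(n) / 1000, coords = coords, fs = 1000),
              class = "landmark_set")
  }
  rep3 <- function(v) matrix(v, n, 3L, byrow = TRUE)
  # horizontal body axis -> chi_xz = 0; vertical dorsoventral axis -> chi_yz = 0
  lm <- mkset(rep3(c(0, 0, 0)), rep3(c(-0.09, 0, 0)),
              rep3(c(-0.02, 0.012, 0)), rep3(c(-0.02, -0.012, 0)))
  ang <- compute_body_angles(lm)
  expect_equal(ang$chi_xz_deg, rep(0, n))
  expect_equal(ang$chi_yz_deg, rep(0, n))
  # body pitched 30 deg up; body rolled so the left shoulder drops 10 deg
  lm2 <- mkset(rep3(c(0, 0, 0)), rep3(-0.09 * c(cos(pi / 6), 0, sin(pi / 6))),
               rep3(0.012 * c(0, cos(pi / 18), -sin(pi / 18))),
               rep3(-0.012 * c(0, cos(pi / 18), -sin(pi / 18))))
  ang2 <- compute_body_angles(lm2)
  expect_equal(ang2$chi_xz_deg, rep(30, n))
  expect_equal(ang2$chi_yz_deg, rep(10, n))

  lm3 <- mkset(rep3(c(0, 0, 0)), rep3(c(0, 0, 0)),
               rep3(c(0, 0.01, 0)), rep3(c(0, -0.01, 0)))
  expect_error(compute_body_angles(lm3), "coincident")
})

test_that("travel angle is signed by the direction of motion", {
  expect_equal(compute_travel_angle(21.9, "left"), 21.9)
  expect_equal(compute_travel_angle(0, "left"), 0)
  expect_equal(compute_travel_angle(10.3, "right"), -10.3)
  expect_true(is.na(compute_travel_angle(15, "hover")))
})

test_that("geometric angle of attack measures the wing-plane tilt", {
  n <- 10
  sh <- matrix(0, n, 3L)
  tip <- matrix(c(0, 0.05, 0), n, 3L, byrow = TRUE)
  p5_flat <- matrix(c(-0.01, 0.03, 0), n, 3L, byrow = TRUE)
  expect_equal(compute_geometric_alpha(sh, tip, p5_flat), rep(0, n))
  p5_vert <- matrix(c(0, 0.03, -0.01), n, 3L, byrow = TRUE)
  expect_equal(compute_geometric_alpha(sh, tip, p5_vert), rep(90, n))
  a <- pi / 4
  p5_45 <- matrix(c(-0.01 * cos(a), 0.03, -0.01 * sin(a)), n, 3L, byrow = TRUE)
  expect_equal(compute_geometric_alpha(sh, tip, p5_45), rep(45, n))
  # collinear frames are interpolated from the neighbours
  p5_bad <- p5_45
  p5_bad[4L, ] <- c(0, 0.02, 0)  # on the span axis
  expect_equal(compute_geometric_alpha(sh, tip, p5_bad), rep(45, n))
})

test_that("bill insertion is the culmen fraction beyond the mouth plane", {
  head <- matrix(c(0.03, 0, 0.25), 5, 3L, byrow = TRUE)
  fwd <- c(1, 0, 0)
  # bill tip exactly at the feeder mouth
  expect_equal(compute_bill_insertion(head, fwd, 0.05, 0.02), rep(0, 5))
  # full culmen inside
  expect_equal(compute_bill_insertion(head, fwd, 0.03, 0.02), rep(100, 5))
  expect_equal(compute_bill_insertion(head, fwd, 0.045, 0.02), rep(25, 5))
  expect_error(compute_bill_insertion(head, fwd, 0.05, 0), "positive")
})

test_that("trial summaries recover the generator's study-condition values", {
  sym <- kinematic_sim_params("hover", wba_ds = 0, wba_us = 0,
                              chi_yz_ds = 0, chi_yz_us = 0, noise_sd_m = 0,
                              n_wingbeats = 10L)
  s <- summarize_trial(simulate_landmarks(sym), "hover")
  expect_equal(s$wba_ds, 0, tolerance = 1e-6)
  expect_lt(abs(s$rwba_ds), 0.01)
  expect_true(is.na(s$psi_deg))

  left <- summarize_trial(
    simulate_landmarks(kinematic_sim_params("left", n_wingbeats = 10L,
                                            seed = 8)), "left")
  expect_equal(left$wba_ds, 4.0, tolerance = 0.3 / 4)
  expect_equal(left$wba_us, 7.9, tolerance = 0.3 / 7.9)
  expect_equal(left$chi_yz_ds, 3.5, tolerance = 0.3 / 3.5)
  expect_equal(left$chi_xz_ds, 59.1, tolerance = 1 / 59.1)
  expect_equal(left$rwba_ds, 7.5, tolerance = 0.5 / 7.5)
  expect_equal(left$psi_deg, 21.9, tolerance = 1 / 21.9)
  expect_equal(left$bill_pct, 24.8, tolerance = 1 / 24.8)
  expect_equal(left$phi_sp_deg, 150, tolerance = 2 / 150)
  expect_equal(left$wingbeat_freq_hz, 41, tolerance = 0.5 / 41)
})

test_that("sagittal mirroring negates WBA, frontal angle and travel angle", {
  lm <- simulate_landmarks(kinematic_sim_params("left", n_wingbeats = 10L,
                                                seed = 13))
  s <- summarize_trial(lm, "left")
  sm <- summarize_trial(reflect_landmarks(lm), "right")
  expect_equal(sm$wba_ds, -s$wba_ds, tolerance = 1e-6)
  expect_equal(sm$wba_us, -s$wba_us, tolerance = 1e-6)
  expect_equal(sm$chi_yz_ds, -s$chi_yz_ds, tolerance = 1e-6)
  expect_equal(sm$chi_xz_ds, s$chi_xz_ds, tolerance = 1e-6)
  # yaw negates; for the opposite travel direction psi is preserved
  expect_equal(sm$psi_deg, s$psi_deg, tolerance = 1e-6)
  expect_equal(sm$rwba_ds, s$rwba_ds, tolerance = 1e-6)
})

test_that("RWBA identity holds on every summary", {
  for (mode in c("hover", "left", "right")) {
    s <- summarize_trial(
      simulate_landmarks(kinematic_sim_params(mode, n_wingbeats = 8L,
                                              seed = 21)), mode)
    expect_equal(s$rwba_ds, abs(s$wba_ds + s$chi_yz_ds), tolerance = 1e-9)
    expect_equal(s$rwba_us, abs(s$wba_us + s$chi_yz_us), tolerance = 1e-9)
  }
  # both aggregation orders are available; they agree when signs are stable
  lm <- simulate_landmarks(kinematic_sim_params("left", n_wingbeats = 8L,
                                                seed = 22))
  a <- summarize_trial(lm, "left", rwba_aggregation = "abs_of_mean")
  b <- summarize_trial(lm, "left", rwba_aggregation = "mean_of_abs")
  expect_equal(a$rwba_ds, b$rwba_ds, tolerance = 0.05)
})

test_that("phase-normalized average wingbeat matches the parametric cycle", {
  par <- kinematic_sim_params("hover", noise_sd_m = 0, n_wingbeats = 10L)
  cyc_ref <- wingbeat_cycle(par)
  cyc <- average_wingbeat(simulate_landmarks(par), "hover")
  expect_equal(cyc$n, 200L)
  expect_equal(sum(cyc$stroke == "down"), 96L)
  expect_equal(cyc$wingbeat_freq_hz, 39, tolerance = 0.5 / 39)
  expect_equal(cyc$stroke_amplitude_deg, 150, tolerance = 2 / 150)
  # elevation and alpha traces track the generator waveforms
  expect_equal(mean(abs(cyc$elev$left - cyc_ref$elev$left)), 0,
               tolerance = 0.5)
  expect_equal(mean(abs(cyc$alpha$left - cyc_ref$alpha$left)), 0,
               tolerance = 3)
})
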