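# hoverkin

Analysis pipeline for docked hummingbird feeding: instrumented-feeder strain
signals, wingbeat kinematics from 3D landmark trajectories, and a
quasi-steady blade-element model of the aerodynamic forces those kinematics
produce.

Hovering hummingbirds feed by docking their bill at a flower or feeder while
keeping station on the wing. Two kinds of measurements characterize how they
control that behavior. First, force sensors on an instrumented feeder record
how a docked bird loads the feeder: licking (10–15 Hz) and wingbeat
(35–45 Hz) oscillations transmitted through the bill, and a slow shift of
the mean signal when the bird pushes sideways against the feeder. Second,
high-speed video of anatomical landmarks captures the wingbeat kinematics —
wing bank, body angles, stroke amplitude, angle of attack — of birds hovering
at a stationary feeder or holding onto one that translates laterally. A
quasi-steady blade-element model converts those kinematics into the
instantaneous and cycle-averaged flight forces, which show that the birds
generate net lateral force *opposing* the feeder's motion rather than flying
along with it. The package is for comparative biomechanists and sensorimotor
physiologists who want a tested, seedable implementation of this chain, with
synthetic-data generators standing in for recorded data.

## The model

Quasi-steady lift and drag on each wing, evaluated at a single blade element
located at the radius of gyration R_gyr = r₂·L and carrying the wing area S:

    |L| = ½ C_L ρ S |V_incident|²        |D| = ½ C_D ρ S |V_incident|²

Lift acts along the unit cross product of the leading-edge vector (shoulder
→ wingtip) with V_incident, oriented upward; drag acts along V_incident.
The incident flow composes three terms,

    V_incident = V_Rgyr + V_induced + V_body

with the wing's own velocity at R_gyr and the body velocity entering
reversed (air relative to wing) and the Rankine–Froude hovering downwash

    V_induced = sqrt(M g / (2 ρ A_disk)),    A_disk = (Φ_sp/180)·π·L²

applied as a uniform downward flow. The lift/drag coefficients are
empirical cosine curves in the aerodynamic angle of attack α_aero (degrees),
one pair per stroke phase, e.g. for the downstroke

    C_L = 0.0031 + 1.5842·cos(0.0301·α_aero + 4.7124)
    C_D = 8.3171 + 8.1909·cos(0.0073·α_aero + 3.1416)

Instantaneous forces are evaluated at 200 equally spaced time points per
wingbeat (48% downstroke, 52% upstroke), expressed in body weights (wb).

Kinematic variables follow the standard conventions for hovering birds:
WBA (wing bank angle) is half the left-minus-right mean wing elevation,
positive with the left wing elevated; RWBA = |WBA + χ_GR,YZ| measures the
bank relative to the frontal body axis; χ_GR,XZ and χ_GR,YZ are the body
angles in the sagittal and frontal planes of the gravitational frame; Ψ is
the travel angle between the wingtip-path dividing line and the feeder
axis, positive facing the direction of motion.

## Worked example

Simulate a feeding trial at the instrumented feeder, calibrate, and run the
strain pipeline:

```r
library(hoverkin)

trace <- simulate_strain_trace(strain_sim_params(seed = 1))
cal <- fit_calibration(simulate_calibration(0.159, noise_sd = 0.005,
                                            n_reps = 3, seed = 2))
cal
#> <calibration_fit> slope 0.1593 V/g, residual RMS 0.004723 V

analyze_strain(trace, list(cal, cal), body_mass_g = 4)$trial
#>         axis n_feeds amplitude_ratio bpr_10_15 bpr_35_45 bpr_60 push_wb
#> 1 horizontal       1            4.77      1676      5073   1.01  0.0797
#> 2   vertical       1            5.00      1716      4461   1.08  0.0515
```

Docking raises the peak-to-peak amplitude about five-fold and floods the
licking and wingbeat bands, while the 60 Hz mains band is unchanged
(ratio ≈ 1); the bird pushes left with ~0.08 of its body weight — the
injected ground truth was 0.32 g on a 4 g bird.

Simulate a left-tracking trial, extract the kinematics, and run the force
model on its phase-normalized average wingbeat:

```r
lm <- simulate_landmarks(kinematic_sim_params("left", seed = 3))
summarize_trial(lm, "left")
#>   psi_deg wba_ds wba_us rwba_ds rwba_us chi_yz_ds bill_pct wingbeat_freq_hz
#> 1   21.92   4.16    7.9    7.61   10.52      3.45    24.81            40.99

net_forces(instantaneous_forces(average_wingbeat(lm, "left")))
#> $vertical_wb  0.753
#> $forward_wb  -0.00653
#> $lateral_wb  -0.103
#> $travel_wb   -0.0977
#> $psi_deg      21.9
```

The bird travels left (+y) with the leading (left) wing elevated
(WBA > 0), yet the cycle-averaged lateral force is negative — about a tenth
of body weight directed *against* the direction of travel — and the
travel-direction component is likewise negative.

`run_demo("out", seed = 1)` runs all three chains (strain, kinematics for
hover/left/right, forces) and writes CSV/JSON outputs plus a plain-text
summary.

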