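---
title: "Methods: strain signals, wingbeat kinematics, and quasi-steady forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain signals, wingbeat kinematics, and quasi-steady forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverkin)
```

hoverkin implements the complete computational chain for studying how
hovering hummingbirds interact with a feeder while docked: the
instrumented-feeder strain-signal pipeline, the extraction of
wingbeat-kinematic variables from digitized 3D landmarks, and a
quasi-steady blade-element model that converts an average wingbeat into
flight forces. This vignette records the scientific assumptions, the
numerical choices, and the limits of what the synthetic-data tests can
show.

## Strain-signal pipeline

A feeding trial is a two-channel voltage record (horizontal and vertical
strain bridges, 1,000 Hz) with dock/undock event times. The pipeline is:

1. **Calibration.** Known masses (2, 5, 10 g by default) hung from the
   feeder give (mass, voltage) pairs; the slope is a least-squares line
   *through the origin*, `sum(m v)/sum(m^2)`, because an unloaded sensor
   reads zero by construction. The residual RMS is reported as a fit
   quality measure.
2. **Feed segmentation.** Each dock interval is cropped by 0.25 s at both
   ends to discard the docking/undocking spike transients. The same 0.25 s
   guard is applied to the dock-adjacent edges of the pre-feed and
   post-feed baseline windows: an undocking transient decays *into* the
   post window, so an unguarded baseline would leak spike energy into the
   detrending fit and break the invariance of all summaries to anything
   that happens within the guard. The required minimum of 3 s of recording
   before the first feed and after the last is validated against the
   unguarded spans. Docks of 0.5 s or less would be emptied by the crop
   and are flagged degenerate and excluded.
3. **Detrending.** An ordinary least-squares line (slope and intercept) is
   fitted to the concatenated pre- and post-feed samples of each channel
   and subtracted from the whole record, removing amplifier drift without
   touching the docked content.
4. **Summaries.** Per feed and axis: the peak-to-peak amplitude ratio
   (docked / pre-dock; values above 1 mean docking increased the signal),
   band spectral-power ratios for the licking (10–15 Hz), wingbeat
   (35–45 Hz) and mains (59–61 Hz) bands, and the push — the docked-minus-
   pre-dock mean shift converted through the calibration slope and
   normalized to body weight (4.0 g in the strain context). Positive push
   is toward the bird's left (horizontal axis) or upward (vertical).

**Spectral estimator.** Band power uses a Welch estimate: 1 s Hann
windows, 50% overlap, one-sided density, trapezoidal integration over the
band. Welch is the stable choice at these record lengths (3–10 s); because
only *ratios* of band powers are reported, the estimate's normalization
convention cancels. The 60 Hz mains reference is widened to 59–61 Hz to be
robust to spectral leakage. No pre-installed R package exposes a Welch
estimator, so the package carries its own thin implementation over
`stats::fft`; a Parseval check against a known tone is part of the test
suite.

**Vertical channel.** It is processed identically to the horizontal one
but its rows carry a quality flag: in the original rig the vertical
calibration was unreliable, which is an acquisition fault rather than an
algorithmic branch.

## Landmark kinematics

Eight landmarks (head, tail, left/right shoulder, wingtip, 5th-primary
tip) at 1,000 frames/s. Axes: x forward along the feeder, y lateral
(positive = bird's left), z vertical up.

1. **Filtering.** Zero-phase fourth-order Butterworth low-pass, with
   cutoffs tied to the wingbeat frequency f: 2f for the head, 6f for
   shoulders and tail, 8f for wingtips and 5th primaries. `filtfilt` alone
   has start-up transients (it applies no end treatment), so signals are
   padded by odd reflection before filtering and trimmed afterwards; this
   makes the filter exact on constant input and translation-equivariant,
   which the test suite checks directly.
2. **Stroke segmentation.** Per wing, a stroke plane is fitted by total
   least squares (principal components) to the shoulder-relative wingtip
   positions, and the in-plane excursion angle is oriented so positive
   points toward the bird's front. Pronation is the per-cycle minimum of
   the excursion, supination the maximum; extremum times are refined to
   sub-frame precision by parabolic interpolation through the three
   samples around each extremum (at 1,000 frames/s and ~40 Hz wingbeats a
   cycle spans only ~25 frames, so integer-frame extrema would quantize
   the frequency estimate visibly). Ties between equal samples resolve to
   the earliest. The wingbeat frequency is the reciprocal of the median
   inter-pronation interval and must fall in a 20–60 Hz plausibility band.
3. **Frame transform.** Every frame is centred on the head (which also
   removes body translation), and each wingbeat is yawed about the
   vertical so the wingtip-path dividing line points along +x. The
   dividing line is constructed per wingbeat from the midpoint of the two
   wings' tip positions at pronation to the midpoint at supination — the
   line that separates the left wingtip path from the right one. Which
   transitions define the line is genuinely open; this construction uses
   both wings symmetrically and is recorded as the package's choice. The
   vertical axis remains gravitational throughout.
4. **Variables.** Wing elevation is the angle of the shoulder-to-wingtip
   vector above horizontal; WBA = (left − right)/2. Body angles come from
   the tail-to-head axis (sagittal elevation, χ_GR,XZ) and the shoulder
   line (frontal tilt, χ_GR,YZ, positive when the dorsoventral axis leans
   toward the bird's left). χ_GR,YZ is stored as *deviation from
   vertical*, the convention under which RWBA = |WBA + χ_GR,YZ| holds
   identically — the package asserts this identity on every summary. The
   travel angle Ψ is the yaw of the dividing line, signed relative to the
   travel direction (positive facing travel); it is reported as `NA` for
   hovering, where it has no meaning. The geometric angle of attack is the
   dihedral angle in [0°, 90°] between the shoulder–wingtip–5th-primary
   plane and horizontal; collinear frames are flagged and interpolated.
   Bill insertion is the percentage of the exposed culmen beyond the
   feeder-mouth plane, with the bill modelled as a segment along the
   head's horizontal forward axis.
5. **Aggregation.** Downstroke/upstroke assignment uses the *detected*
   pronation–supination intervals (the left wing's intervals for body
   variables, each wing's own for its elevation means); the fixed 48:52
   split is used only for the phase-normalized average wingbeat passed to
   the force model, matching the model's stated assumption. The first and
   last detected cycles are dropped to avoid filter and segmentation edge
   effects. Whether RWBA is the absolute value of the trial means
   (default) or the mean of per-wingbeat absolute values is a config
   switch (`rwba_aggregation`): the two orders differ when WBA + χ changes
   sign between wingbeats, and neither is asserted as the original
   intent.

## Quasi-steady force model

The model evaluates a single blade element at the radius of gyration
R_gyr = r₂·L carrying the full wing area S. Defaults (Anna's hummingbird
species averages): S = 6.78e-4 m², L = 0.0525 m, r₂ = 0.499,
M = 4.68 g, ρ = 1.18 kg/m³. A chord-wise multi-blade integration would
need a spanwise velocity and area distribution that the single-element
formulation deliberately collapses into R_gyr and S.

- **Incident flow.** V_incident sums the reversed wing velocity at R_gyr
  (finite central differences over the 200 equally spaced time points,
  with periodic wrap), the reversed body velocity, and the Rankine–Froude
  hovering downwash applied as a constant downward flow. The hovering
  induced-velocity equation is used for all modes because the 0.15 m/s
  lateral speed is far below the ~1 m/s threshold where the forward-flight
  form matters. Whether the downwash differs between half-strokes is not
  resolvable from a momentum-theory argument; it is held constant over the
  cycle and that assumption is recorded here. The disk area uses
  A_disk = (Φ_sp/180)·π·L² as defined for this model, even though at
  Φ_sp = 360° it equals twice a full disk; the induced velocity enters
  only under a square root, so the consequences are modest and consistent.
- **Coefficient curves.** The empirical cosine fits use a mixed-unit
  convention: the angle of attack in degrees is multiplied by a per-degree
  frequency constant and added to a radian phase (4.7124 ≈ 3π/2,
  3.1416 ≈ π), with the cosine evaluated in radians. This is the only
  reading under which C_L,down(0°) ≈ 0 and C_D,down(0°) is minimal, as a
  thin wing requires. The upstroke curves are parameterized in
  α_aero − 180: the package computes the unsigned angle β between the wing
  plane and the incident flow and evaluates the upstroke curves at
  180 + β, under which C_L,up is positive at physical angles of attack and
  crosses zero at β = 0.
- **Directions.** The leading-edge vector is taken as shoulder → wingtip:
  for a hummingbird wing the leading edge runs essentially span-wise from
  the shoulder, and no finer definition is available from three points
  per wing. Lift acts
  along unit(leading-edge × V_incident) flipped, if needed, to a positive
  vertical component; drag acts along V_incident. Points with vanishing
  incident speed get zero force rather than NaN.
- **Averages.** The 200 points are equally spaced in *time* (96 points in
  the 48% downstroke, 104 in the 52% upstroke), so cycle averages are
  unweighted means. Net forces are reported in body weights in the
  bird-centred frame; the travel-direction component projects the mean
  force onto the global travel axis rotated into that frame.

The model satisfies, and the tests verify: exact left/right force
mirroring for symmetric kinematics, reflection equivariance (mirroring the
kinematics negates lateral outputs only), linearity in ρ and S at fixed
incident flow, quadratic scaling in speed, lift ⊥ flow and drag ∥ flow to
1e-10, and agreement within 0.5% between 200-point and 10,000-point
evaluations of the same continuous kinematics.

## Synthetic-data generators

The generators exist so every downstream stage is testable without the
original recordings; their defaults *are* the experimental conditions.

**Strain traces** superpose, on each channel: linear drift and 60 Hz mains
(whole record); licking (12 Hz default, within 10–15), wingbeat (40 Hz
default, within 35–45) and a push offset (gram-equivalents × calibration
slope) only inside dock intervals; one-sided exponential spike transients
(20 ms time constant) at dock and undock, placed so the 0.25 s crop must
remove them; and white Gaussian sensor noise. Default push 0.32 g on a 4 g
bird (0.08 wb) matches the scale of the measured lateral responses;
default calibration slope 0.159 V/g is the rig's horizontal-axis mean.

**Landmark trajectories** place a bird with the body pitched, rolled and
yawed per the mode's χ angles and travel angle; wingtips follow a
piecewise-cosine excursion waveform implementing the 48:52
downstroke:upstroke split (half-cosines of unequal duration are the
simplest waveform with the right phase structure and continuous
velocity at the transitions); per-wing elevation and the body angles blend
smoothly between their downstroke and upstroke targets through a
single-harmonic carrier solved to hit both phase means exactly. The
geometric angle of attack runs from 90° at the stroke reversals to a
mid-stroke value (default 45°), with a per-wing timing shift (±2% of the
cycle in tracking modes) implementing the delayed rotation of the leading
wing and advanced rotation of the trailing wing. Mode defaults follow the
experimental trial means: 39 Hz hovering / 41 Hz tracking wingbeats; WBA, χ,
Ψ and bill-insertion values per mode; 0.15 m/s feeder speed. No measured
stroke amplitude is available for these conditions; the default
Φ_sp = 150° is a mid-range hovering value for this species, chosen once.
Digitization error is additive Gaussian noise (default 0.1 mm).

What the generators do *not* emulate: camera projection and DLT
reconstruction error structure (only isotropic Gaussian noise), wing
deformation and twist (the wing is a rigid plane through three points),
feather-level kinematics, and any feedback from forces back onto the
kinematics. Passing round-trip tests therefore demonstrates that the
pipeline recovers the parameters of data *with this structure*; it cannot
certify behavior on real video noise or deforming wings.

## Problem sizes and runtime choices

Tests and the acceptance script use 8–12 wingbeats per kinematic trial,
~10 s strain records, 20–50 seeded replicates for recovery statistics, and
10,000-point refinement checks; these sizes give stable estimates (the
push-recovery error is well under 1% and the refinement discrepancy under
0.5%) while keeping a full run in seconds.

## Known limitations

- Quasi-steady only: rotational lift, added mass and wake capture are
  outside the model by definition, and the rigid-plane angle of attack
  overestimates drag-derived forward thrust during the upstroke when real
  wings twist.
- The travel angle and the lateral-force sign conventions assume purely
  lateral feeder motion along the global y axis.
- The strain pipeline's statistics stop at per-feed and per-trial
  summaries; mixed-effects modelling across birds/trials is deliberately
  out of scope and the summary CSVs are the interface to external
  statistics packages.
- The hovering RWBA is near zero, where the two RWBA aggregation orders
  legitimately disagree at the 0.1° level; both are provided.
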