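# pierisflight

Quantifying butterfly flight behaviour from stereo high-speed video, and
relating it to wing morphology.

Seasonally polyphenic butterflies such as *Pieris napi* and *P. rapae*
produce spring and summer generations with different wing sizes and shapes,
and those shapes are widely assumed to matter for flight. Testing that
assumption requires (i) reconstructing free-flight trajectories in three
dimensions from paired cameras, (ii) reducing each trajectory to
interpretable flight parameters, (iii) measuring wing size and shape from
landmarked specimens, and (iv) a statistical layer that compares species,
seasonal forms and sexes while respecting repeated measures per individual.
`pierisflight` implements that entire workflow, together with a
synthetic-data generator that produces every input with known ground truth,
so each stage is testable without any field recordings.

## Methods at a glance

**Stereo reconstruction.** Cameras follow the 11-coefficient direct linear
transformation (DLT): a world point $(x,y,z)$ maps to pixels by

$$u = \frac{L_1 x + L_2 y + L_3 z + L_4}{L_9 x + L_{10} y + L_{11} z + 1},
\qquad
v = \frac{L_5 x + L_6 y + L_7 z + L_8}{L_9 x + L_{10} y + L_{11} z + 1},$$

with optional one-parameter radial lens distortion handled at the point
level. Calibration is available from known 3D targets (`dlt_calibrate()`)
or, as in field practice, from a rigid two-point wand of known length moved
through the volume (`wand_calibrate()`): both cameras and all wand
endpoints are estimated jointly by nonlinear least squares on reprojection
error plus a wand-rigidity term, with metric scale fixed by the wand length
and the vertical axis fixed by a plumb reference. `triangulate()` inverts
the two-camera DLT system per frame by linear least squares.

**Trajectory smoothing.** A constant-acceleration Kalman filter (state =
position, velocity, acceleration per axis; white-jerk process noise) with a
Rauch–Tung–Striebel backward pass smooths the 3D track, estimates positions
for frames that could not be digitised, and supplies the velocity and
acceleration used by all downstream kinematics. `tune_noise()` selects the
noise parameters from the data on a fixed grid by one-step predictive
likelihood.

**Flight parameters.** `summarize_flight()` computes, per trajectory:
wingbeat frequency (counted wingbeats / duration), covered distance, mean
flight height, mean speed $\overline{|v|}$, mean acceleration
$\overline{|a|}$, advance ratio $\overline{|v|}/f_{wb}$, turning
acceleration $\overline{|v \times a|/|v|}$ (centripetal component), turning
rate (angular change of the velocity direction per second), sinuosity
(straight distance / covered distance, in [0, 1]), flight curvature
$\overline{|v \times a|/|v|^3}$, and signed ascent angle
$\arcsin(v_z/|v|)$.

**Wing morphometrics.** From 19 labelled forewing landmarks plus digitised
outlines: forewing length (landmark 1 to 13), maximum perpendicular width,
aspect ratio, polygon (shoelace) wing areas, cylindrical thoracic volume as
a body-mass proxy, wing loading, the outer-edge curvature index (polyline
length 13→19 over its chord, 1 = straight margin) and the relative
marginal-region length (distance 1–9 over 1–13).

**Statistics.** Pearson correlation matrices; two-way ANOVA (species ×
seasonal form); PCA with deterministic EM imputation of missing
wingbeat-derived values; per-parameter linear mixed models
`log(response) ~ species + form + sex + log(covered distance) +
(1 | individual)` with Satterthwaite F-tests (lme4/lmerTest); marginal
means with Tukey contrasts (emmeans); Cohen's *d* as slope/SE; stepwise
backward elimination; and all-subsets AICc ranking with per-variable Akaike
weight sums.

## Worked example

Calibrate a rig from a wand sweep, then push a noisy rendered flight
through the full pipeline:

```r
library(pierisflight)

# synthetic recording scene: 6 x 2.5 x 2.5 m cage, two perpendicular
# cameras on 0.8 m tripods, 120 fps, 2560 x 1440 px, 0.5 px pixel noise
scene <- scene_config(pixel_noise_sd = 0.5)

# wand calibration from 120 poses of a 24 cm wand
obs <- generate_wand_sweep(scene, wand_length = 0.24, n_poses = 120, seed = 1)
cal <- wand_calibrate(obs, vertical_ref = render_vertical_ref(scene))
cal
#> <wand_calibration> 120 poses; wand length 0.2400 m (SD 2.95e-03 m);
#>   reprojection RMS 0.272 px

# a helical flight (true speed 1.5 m/s, true curvature 1.923 1/m),
# rendered to two pixel tracks, reconstructed and summarised
path <- generate_flight_path(path_profile("helix", speed = 1.5, radius = 0.5,
                                          pitch = 0.1, duration = 2.5,
                                          start = c(3, 1.25, 1.0)))
tracks <- render_pixel_tracks(path$traj, scene, seed = 2)
traj   <- triangulate(tracks[[1]], tracks[[2]],
                      cal$cameras[[1]], cal$cameras[[2]])
states <- kalman_smooth(traj)             # q, r tuned from the data
summarize_flight(states, wingbeat_record("demo", 28, 2.5))
#> mean_velocity        1.502   # true 1.5 m/s
#> flight_curvature     1.933   # true 1.923 1/m
#> turning_acceleration 4.358   # true 4.327 m/s^2
#> sinuosity            0.225
#> advance_ratio        0.134
#> ...
```

The reconstructed wand length (24.00 cm, SD ~3 mm under 0.5 px noise) is
the calibration quality score; the flight parameters land within ~1% of
their closed-form helix values after smoothing.

A complete synthetic study — cohort simulation, calibration,
triangulation, smoothing, kinematics, morphometrics and the statistical
tables — runs end-to-end with

```r
run_pipeline(run_config(system.file("extdata", "demo_config.yaml",
                                    package = "pierisflight")))
```

or from a shell via `inst/scripts/flightpipe.R` (subcommands `simulate`,
`calibrate`, `triangulate`, `smooth`, `kinematics`, `morpho`, `stats`,
`run-all`, `validate`).

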