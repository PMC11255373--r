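---
title: "From stereo video to flight parameters: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stereo video to flight parameters: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pierisflight)
```

`pierisflight` reconstructs three-dimensional butterfly flight trajectories
from paired camera tracks, reduces them to eleven flight parameters,
measures wing morphology from landmarked specimens, and compares species,
seasonal forms and sexes with mixed models. This vignette explains the
models behind each stage, the tunable parameters and why their defaults
were chosen, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the methods literature leaves the
choice open.

## The camera model and calibration

Each camera is an 11-coefficient direct linear transformation (DLT): a
projective 3×4 matrix normalised so its last element is 1. The DLT is the
standard model in animal videogrammetry because it is linear both to
calibrate (given 3D–2D correspondences) and to invert (triangulation), and
because wand-based field calibration tooling exchanges exactly these 11
coefficients per camera. Wide-action-camera lenses add barrel distortion;
we model it as a one-parameter radial (Brown) map about the geometric image
centre, with the radius normalised by the image half-diagonal so the
coefficient is dimensionless and comparable across resolutions.
Undistortion inverts the map by fixed-point iteration to below 1e-8 px;
the iteration diverges only for distortion far stronger than any real
lens, and that failure is reported rather than silently accepted.

**Known-point calibration** (`dlt_calibrate()`) solves the linear DLT
system in least squares and stores the *geometric* reprojection RMS (per
pixel coordinate), not the algebraic residual of the linear system — the
two differ by the projective denominator, and only the former is
interpretable in pixels. At least six non-coplanar points are required;
coplanarity is detected from the third singular value of the centred point
cloud, since a coplanar target leaves the projective model underdetermined.

**Wand calibration** (`wand_calibrate()`) estimates both cameras and all
wand endpoints jointly from tracked images of a rigid two-point wand. Two
fully projective DLT cameras are *not* identifiable from reprojection
error alone — any projective remap of the scene reprojects identically —
so the optimisation runs over a constrained pinhole parameterisation: one
focal length per camera, principal point fixed at the image centre, square
pixels, plus the relative pose (7 parameters). Even then a classical
degeneracy remains: when the two optical axes are coplanar (they are, in
any rig where both cameras aim at the centre of the working volume), the
focal lengths are not determined by the image correspondences. The wand
itself resolves this: the objective adds the relative variation of the
reconstructed endpoint separation ("rigidity") to the pixel residuals,
weighted so 1% length scatter counts like 1 px (weight 100). The
optimisation is variable-projection Levenberg–Marquardt — endpoints are
re-triangulated linearly inside every residual evaluation — initialised by
a normalized 8-point essential-matrix estimate; because that initialisation
itself depends on an assumed focal length, a four-point multi-start over
plausible focal guesses is run and the best refined optimum kept. The
procedure is deterministic given the input.

The reconstruction gauge is fixed explicitly, since "flight height" and
"ascent angle" are only meaningful in a gravity-aligned metric frame:
scale is set so the mean reconstructed wand length equals the known wand
length (0.24 m by default); the z axis is aligned to a digitised plumb
(vertical reference) segment, or to camera 1's image "up" when none is
given; the y axis follows the horizontal component of camera 1's view
direction; the origin sits at the centroid of the wand cloud, with z = 0
re-anchored to the ground plane whenever the vertical reference records
the height of its lower end. The world origin is deliberately *not* placed
at camera 1's optical centre: a DLT normalised to L12 = 1 cannot represent
a camera whose principal plane contains the origin. The per-frame
reconstructed wand lengths (mean, SD) are returned as the calibration
quality score, as is conventional.

Triangulation stacks the four DLT constraint rows of a frame and solves
for the 3D point in linear least squares; frames seen by only one camera,
or whose system is ill-conditioned (near-parallel rays, singular-value
ratio above 1e6), are flagged invalid and left to the smoother.

## Trajectory smoothing

The smoother is a per-axis linear Kalman filter with state (position,
velocity, acceleration), constant-acceleration transition and white-jerk
process noise of spectral density `q` (m²/s⁵), followed by a fixed-interval
Rauch–Tung–Striebel backward pass. The backward pass is the standard
offline choice: every state estimate is conditioned on the whole
trajectory, which roughly halves edge lag and is what makes the
acceleration state usable for curvature. A filter-only mode
(`smooth_pass = FALSE`) is kept for sensitivity checks. Frames missing
from the input receive prediction-only updates, so the smoother also
supplies the missing positions, flagged `estimated = TRUE`.

All downstream kinematics take velocity and acceleration from the Kalman
state rather than finite differences: differencing noisy positions
amplifies noise quadratically in the second derivative, while the
state-space estimate is regularised by the motion model and is
self-consistent with the gap filling.

Noise parameters matter mostly through the ratio q/r. `tune_noise()` is
deterministic: a pilot pass seeds the measurement variance from the median
squared innovation (rescaled by the χ²₁ median, 0.4549, so the median is
an unbiased scale estimate under Gaussian innovations), then a fixed 5×5
log-spaced grid over (q, r) is scored by summed one-step predictive
log-likelihood. The q grid spans 10⁻²–10⁶ m²/s⁵, which brackets everything
from near-ballistic gliding to erratic fluttering at these body sizes; the
r grid spans a factor of 10 around the pilot estimate. On rendered
trajectories with ~1 px pixel noise the tuned smoother recovers helix
curvature to well under 1%; over-large q (too permissive a motion model)
is the main failure mode, inflating curvature through acceleration noise,
and the likelihood criterion reliably avoids it.

The first and last five frames of each smoothed track are treated as
burn-in and excluded from every summary statistic, removing filter
initialisation and boundary effects at a cost of 1/24 s per end.

## The eleven flight parameters

Definitions follow the standard verbal descriptions, made exact as
follows; all averages are means of per-frame magnitudes (not magnitudes of
mean vectors), a choice that must be stated because the two differ for any
curved flight:

- turning acceleration is formalised as the centripetal component
  |v × a| / |v| — the part of acceleration strictly attributable to
  direction change;
- flight curvature is the frame-averaged differential-geometric
  κ = |v × a| / |v|³;
- turning rate uses the two-argument arctangent of cross- and dot-product
  magnitudes between successive velocity vectors, which is numerically
  stable for both tiny and near-π angles;
- sinuosity is straight distance over covered distance, clamped to [0, 1]
  (note this is the *reciprocal* of the common movement-ecology index:
  1 = straight here);
- ascent angle is averaged with sign (descent negative); an absolute-value
  variant is available by flag;
- advance ratio is mean speed over wingbeat frequency — metres advanced
  per wingbeat. Wingbeat counts are input metadata (counted during video
  scoring); a missing count propagates a missing frequency and advance
  ratio, to be imputed in the statistical layer rather than guessed here.

Frames with speed below 1e-6 m/s are excluded from direction-based
quantities, whose denominators vanish at rest.

## Wing morphometrics

Measurements operate on 19 labelled forewing landmarks (1 = wing base,
13 = outer end of the length axis, 13–19 = outer-margin vein ends, 9 =
marginal-region end) plus digitised outlines, all in mm. Wing areas come
from the shoelace formula on the outline polygons — deterministic and
exactly testable, unlike pixel-histogram thresholding, while measuring the
same quantity. The thorax is modelled as a cylinder with the measured
width as *diameter*; thoracic volume serves as the body-mass proxy in wing
loading (volume over total wing area, with both a cm³/cm² and the
conventional mm³/mm² output, which differ by exactly 10). Outlines are
validated as simple polygons; a damaged specimen that cannot supply all 19
landmarks is rejected at construction, mirroring how such specimens are
excluded in practice. Right-wing digitisations are mirrored at ingest so
all downstream geometry is side-agnostic. Every derived measurement is
invariant under rotation, translation and reflection and scales with the
correct power of a uniform rescaling (length¹, area², volume³, indices⁰);
these equivariances are enforced by tests at 1e-9.

## The synthetic-data generator

The generator exists so that each stage can be validated against known
truth. Its scene defaults are the study conditions: a 6 × 2.5 × 2.5 m
cage, two perpendicular cameras on 0.8 m tripods, 120 fps, 2560 × 1440 px,
and a 0.24 m calibration wand. The default camera focal length (1200 px)
is chosen so the whole cage fits the sensor from the tripod positions,
matching a wide action-camera field of view; lens distortion defaults to
zero because the emulated recordings are undistorted upstream of
digitisation, and a nonzero coefficient is exercised in tests.

Path profiles (straight, circle, semicircle, helix, flutter, correlated
random walk) carry ground-truth kinematics: closed forms for the analytic
shapes, numerically integrated truth for flutter and the random walk. The
flutter profile superimposes a vertical sinusoid at the wingbeat frequency
so wingbeat metadata stays consistent with path geometry. Rendering
projects through the scene cameras, applies distortion, Gaussian pixel
noise and i.i.d. frame dropout, and flags points outside the sensor or
behind a camera.

Cohort generation is hierarchical and mirrors the study design: 31
individuals in the observed species × form × sex cells, 106 tracks
(26 spring / 80 summer, 1–6 per individual), lognormal parameter variation
with an individual-level random intercept and a track-level residual (both
SD 0.25 on the log scale — calibrated so the implied marginal-mean
standard errors match the published ones, e.g. ~0.12 m/s for spring
velocity), group means at the published seasonal marginal means (velocity
1.2/1.7 m/s, acceleration 2.31/3.43 m/s², advance ratio 0.10/0.14 m,
turning acceleration 1.30/2.34 m/s², curvature 3.80/1.53 m⁻¹; these are
treated as response-scale geometric means, since the source does not state
the scale), and four tracks with the wingbeat count left missing. Each
track also carries a helix profile whose closed-form speed and curvature
equal its drawn values, so a parameter row can be re-realised as an actual
3D trajectory; the other parameters of such a re-realised path follow from
helix geometry rather than the drawn values — the table, not the path, is
the sampling unit for the statistics. Parameters that the study found
indistinguishable between forms (wingbeat frequency, height, turning rate,
sinuosity, ascent angle) default to equal group means; their values
(11 Hz, 1.1 m, 3.5 rad/s, 0.75, 2°) are field-plausible for pierids.
Morphology targets come from the published group summaries (male rows;
the female wing-loading cells are internally inconsistent in scale and are
not emulated), with per-specimen geometry built to hit its drawn targets
*exactly*, so group means are unbiased; the drawn forewing area and aspect
ratio are correlated at −0.40 as observed. Ambient temperatures are drawn
per recording day from a Beta(1.5, 5.1) stretched over 14–36 °C (mean
≈ 19 °C, matching the reported range and mean) with zero true effect, so
the temperature models can be checked for calibration.

What the generator does *not* emulate: wingbeat-resolved body dynamics,
behavioural state switching, camera synchronisation error, digitisation
bias (noise is i.i.d. Gaussian), or any real correlation structure among
the eleven parameters beyond what the shared individual intercept and the
helix realisation induce. Passing tests therefore demonstrate correctness
of the algorithms under the stated noise model, not fidelity of any
biological conclusion drawn from real footage.

## Statistical layer

Responses are natural-log transformed when strictly positive; ascent angle
carries sign and is analysed untransformed with a note — a blanket log
transform is ill-defined there, and this is the one place the package
departs from a uniform rule. Each flight characteristic is modelled
separately as `log(y) ~ species + form + sex + log(covered distance) +
(1 | individual)`, REML, with Satterthwaite denominator degrees of freedom
(lmerTest), chosen to mirror the fractional dfs conventional in this
literature. A fit whose random-intercept variance collapses to zero (or a
design with one track per individual, where it is unidentifiable) is
flagged singular and refit as a fixed-effects model with a warning, rather
than reporting a boundary estimate as if it were informative. Marginal
means are computed at the reference grid with Tukey-adjusted pairwise
contrasts and back-transformed to the response scale (delta-method SEs)
when the model is on the log scale.

Missing wingbeat frequency and advance ratio are completed by iterative
EM-PCA before ordination: standardise by observed column SDs, initialise
missing cells at column means, then alternate rank-`ncp` SVD
reconstruction of the missing cells with re-estimation of the column
means, to a 1e-8 convergence tolerance. The per-iteration mean
re-estimation matters: with means frozen at their observed-cell values the
fixed point is biased, and an exactly low-rank matrix would not be
recovered. With nothing missing the procedure reduces exactly to PCA.

Morphology-to-flight models use the five log-transformed morphological
variables plus log covered distance and sex, individual as random
intercept. Effect sizes are Cohen's *d* = slope/SE. Stepwise backward
selection removes, at each step, the morphological term with the largest
Satterthwaite p-value above α = 0.05 (the threshold is our choice; the
procedure's description names no value) and never touches the covariates —
which is why it is implemented in-package rather than delegated to a
generic stepper that would also prune covariates and random terms. The
all-subsets ranking refits every subset of morphological terms by maximum
likelihood (information criteria are not comparable across REML fits with
different fixed effects), ranks by AICc = AIC + 2k(k+1)/(n−k−1), and
reports Akaike weights and per-variable weight sums; the candidate set is
capped at 12 terms (4096 models). P-values across the ~11 response
variables are deliberately *not* adjusted for multiplicity, matching the
comparative convention in this literature; users combining many responses
should apply their own correction.

## Problem sizes and determinism

Every stochastic component is a pure function of an integer seed: cohort
and path generation save and restore the global RNG state, so library
code never perturbs a user's random stream. The test suite checks the
statistical operating characteristics at simulation sizes chosen to keep
the whole suite near two minutes on one core: type-I error of the
seasonal-form F-test over 1000 null cohorts (accepted in [0.03, 0.07]),
power against the published velocity gap over 200 cohorts (required
> 0.8), 20-seed full-pipeline recovery, and 100-seed calibration-residual
distributions. The pipeline demo renders two tracks end-to-end in a few
seconds; rerunning any stage with the same configuration and seed
reproduces its CSVs byte-for-byte.

## Known limitations

- Two cameras only; no multi-camera bundle, rolling-shutter or
  synchronisation-offset modelling.
- The pinhole constraint (square pixels, centred principal point) is what
  makes wand calibration well-posed here; a lens whose principal point is
  far off-centre would bias the reconstruction.
- Wand calibration assumes undistorted input tracks; distortion is
  estimated nowhere in the wand path (point-level undistortion with a
  known coefficient is available).
- The advance ratio is the simplified distance-per-wingbeat, not the
  aerodynamic advance ratio (which needs wingtip speed).
- EM-PCA imputation assumes missingness unrelated to the missing value
  (wingbeats unscorable for visibility reasons, not because of their
  value), adequate for the few-cells-missing regime it serves.
- The landmark generator produces one family of wing shapes parameterised
  by the four target indices; it spans the observed index ranges but is
  not a morphospace of real *Pieris* wings.
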