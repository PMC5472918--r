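---
title: "Methods: models, calibration and design choices in ethoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in ethoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoscreen)
```

# The assay and its data

`ethoscreen` analyzes the walking behavior of individual flies in a
vertical 150 mm × 50 mm arena, sampled at 0.25 s per frame. The package
takes the tracker's output — one (x, y) centroid per frame per fly — as
its input contract; video processing is upstream and out of scope. The
coordinate convention is origin at the bottom-left with y increasing
upward, so gravity points toward y = 0 and a "slip" is a sharp decrease
in y. Uniform sampling is a hard assumption: every kinematic formula
operates on fixed 0.25-s sub-segments, so frame gaps are rejected as
errors rather than interpolated.

# Kinematic parameters

Movement is quantified in non-overlapping 5-s segments of 20 sub-segment
displacement vectors. Speed is total path over 5 s; acceleration is the
mean absolute difference of consecutive sub-segment speeds divided by
0.25 s; stop duration counts sub-segments whose displacement falls below
0.1 mm (about a tenth of a body length, the tracker's meaningful
resolution); locomotory rate divides the path by the *moving* time only
and is therefore undefined (NA) on a fully stopped segment; meander
accumulates absolute heading changes between consecutive moving
sub-segments per unit of moving path (rad/mm) and needs at least two
moving sub-segments to be defined.

Three conventions deserve comment because more than one reading is
defensible:

- **Meander is per distance, not per time.** The rad/mm unit fixes the
  definition; an "angular change divided by time" reading would have
  units rad/s and is treated as a description slip.
- **Acceleration uses absolute differences.** Group mean accelerations
  are positive quantities; a signed mean would hover near zero for any
  stationary gait.
- **The stop comparison is strict** (`< 0.1 mm`), with a 1 nm
  floating-point guard so that a displacement of exactly 0.1 mm always
  counts as movement regardless of accumulated rounding in coordinate
  arithmetic.

**Slip detector.** A slip event is a maximal run of consecutive
sub-segments whose downward vertical displacement exceeds 2 mm per frame
(8 mm/s downward, roughly twice the fastest group-mean walking speed, so
ordinary downward walking cannot trigger it). Each maximal run counts
once; the threshold and the run-merging rule are package decisions, since
"slip" has no standard operational definition. The per-segment count is
stored raw; reporting can rescale to other time bases.

**Zones.** The arena's top and bottom bands default to 20% of the height
each and the food region to a 20 mm × 10 mm rectangle centered on the
bottom edge. These extents are conventions, not measurements — the assay
literature names the areas without defining them — and are configurable
on the `arena` object. The food region takes precedence over the bands
so a point maps to exactly one zone.

# Box-counting fractal dimension

For a window of track points, the estimator counts occupied cells of a
grid of side r anchored at the arena origin and fits
log N(r) ~ D·log(1/r) by least squares over a dyadic ladder from 75 mm
(half the arena height) down to 0.5 mm. The floor of 0.5 mm is about five
times the 0.1-mm movement resolution, so tracker jitter is not counted as
structure. Numerical choices: the grid is anchored (no offset averaging)
to keep the estimator deterministic — a robustness test verifies the
line fixture stays within 1.0 ± 0.1 when the scale range is halved or
doubled — and all supplied scales enter the fit (no automatic
scaling-region selection, for which there is no principled rule here).
A degenerate fit (all counts equal, e.g. a single repeated point) is
flagged and reported as D = 0 rather than extrapolated. The default
window is 30 min of track; the window length is configurable because
shorter readings are plausible and the estimate grows with window length
(more points fill more cells), so windows must never be compared across
different lengths.

# SOM ethogram

The six parameters of every segment are min–max scaled to [0, 1] with the
bounds stored in the model, so later data are classified on the training
scale (out-of-range values clip, with a count). Undefined meander and
locomotory-rate entries are imputed as 0 *after* scaling: a fully stopped
segment genuinely is minimal-activity input, and the imputation flags are
retained rather than discarded.

The map is 14 × 10 (140 nodes, following the ≈ 5√n sizing heuristic with
the longer side vertical), trained by random-sample sequential updates:
the best matching unit (BMU) is the Euclidean argmin over nodes (ties to
the lowest index), and weights move toward the input under a Gaussian
neighborhood, `w <- w + α·exp(-d²/(2·radius²))·(x - w)`. The schedule —
a rough phase (10 passes, α 0.5→0.05, radius 5→1) then a fine phase (40
passes, α 0.05→0.01, radius 1→0.5), both linearly decayed — and the
Gaussian kernel are package decisions; SOM practice varies and no single
standard exists. Initialization is linear along the first two principal
components (the larger spanning the 14-row axis), which is deterministic,
makes the dominant activity gradient land on the vertical axis of the
map, and leaves the seed to control only the presentation order; training
is bit-reproducible given seed and data. The training loop is compiled
(Rcpp) with all randomness and schedules precomputed in R; a unit test
pins the compiled update to the R reference implementation.

The codebook is clustered with Ward linkage (`ward.D2`) on the Euclidean
distance matrix, heights rescaled to 0–100%, cut at k = 9, and cluster
IDs are dendrogram-ordered (leftmost leaves first) since the alternative
map-geometry numbering is ambiguous. The nine clusters map onto four
patterns with fixed sizes 3/1/3/2 by profile rules: the two lowest-speed
clusters are *stop*; of the rest, the three highest-meander clusters are
*zigzag*; of the remaining four, the highest meander-to-speed ratio is
*circling* and the other three are *active*. Rule-based labeling replaces
the visual inspection such maps are usually labeled by; the fixed
partition sizes are taken as given. A codebook with no activity gradient
(constant speed) cannot be labeled and errors out.

# The synthetic cohort generator

No behavioral recordings are distributed with the assay, so the simulator
is a first-class, tested module: every downstream stage is exercised
against data with known ground truth. Its generative model is the
simplest structure able to realize the six parameters independently:

- a two-state (move/stop) Markov chain per 0.25-s step, with entry/exit
  probabilities setting both the stop-time fraction and the bout
  lengths;
- while moving, step length ~ positive-truncated normal and heading =
  previous heading + N(0, turn_sd), blended toward "up" with weight
  `geotaxis_drift`; within 10 mm of the top edge the upward blend turns
  into wall-following (blending toward the nearer horizontal direction),
  because a fly that has satisfied its negative geotaxis walks the edge
  rather than pushing into it;
- while stopped, displacement is uniform below 0.1 mm;
- slip events arrive as a thinned per-step Poisson process and insert
  1–3 consecutive steep downward steps totaling ≈ `slip_depth_mean`
  (default 2.08 mm, one step), with a one-step refractory gap so
  consecutive events never merge into one detected run;
- a step that would leave the arena is reflected (component sign flip)
  *before* it is taken, which preserves the step length exactly — wall
  contact therefore does not bias measured speed.

**Calibration.** Preset nominals are *observables*: `move_speed_mean` is
the target measured per-segment speed and `slip_rate` the target detected
slips per 5 s. The generator solves the per-segment path budget
(slip path + moving path + stop jitter = 5 s × speed) for the
truncated-normal location of the moving step (`uniroot` on the
truncated-normal mean), and inverts the renewal equation of the slip
process (one event occupies its run plus the refractory step) for the
per-step trigger probability. This makes recovery well-posed: an
estimator reading the nominal back from simulated data is checked against
Monte-Carlo standard errors, not against an uncalibrated input.

**Slip saturation.** Slips cost height, and height must be re-climbed.
The sustainable event rate is bounded by the upward flux of the moving
path; the generator estimates that bound from the stationary heading
spread (an AR(1) walk around "up" gives spread `turn_sd/√(1-(1-drift)²)`
and mean upward fraction `exp(-spread²/2)`) and budgets with the
saturated rate. For heavily intoxicated presets the nominal slip rates
(up to 4.03 per 5 s) exceed what their own movement budget can sustain
with 2-mm falls, so their *realized* detected rates saturate lower
(≈ 1.4–2.5 per 5 s) while remaining far above control rates. This is a
physical constraint, not a tuning artifact, and it is why absolute slip
recovery is only asserted for the (unsaturated) wild-type control preset.

**The nine default presets** fix nominal speeds and slip rates at the
published group statistics (wild-type 3.52 mm/s / 0.85 slips, *p38b*
4.22 mm/s, *p53* 2.72 mm/s before treatment; treated speeds 2.18–3.12
mm/s; *p53* treated speeds are not printed and are set to plausible
values 2.10/2.25 mm/s). The remaining parameters are not published
anywhere and were chosen so the preset contract holds robustly: stop
fractions 0.26–0.36 of segment time for controls versus 0.38–0.44
treated; control gaits are bursty (moving-speed SD 1.5–2.6 mm/s,
frequent brief pauses) while treated gaits are sluggish and low-variance
— this contrast is what keeps group-mean acceleration higher in controls
even though slip impulses add large speed jumps to treated segments;
geotaxis drift 0.15–0.18 for controls and 0.18–0.60 for treated presets.
Simulated sessions default to 30 min per individual — the window length
of the fractal analysis and of the recovery checks — rather than the
full 6-h observation sessions of the assay design, purely to keep
simulation sizes proportionate; nothing in the generator depends on the
session length.

**What the generator does not emulate.** No odor plume or dose-response
kinetics (a treatment is a static behavioral state, not a time course);
no tracker noise beyond the sub-0.1-mm stop jitter; no interaction with
the food region by default (`food_attraction` exists but defaults to 0);
no inter-individual variability in the nominal parameters (all
individuals of a group share one preset; between-track variance arises
from the dynamics only, so simulated group SDs understate real ones).
Passing recovery and direction tests on these cohorts therefore shows
the *estimators and pipeline* are correct and the presets encode the
intended contrasts — it does not validate the biological model against
real flies.

# Group statistics

Summaries report mean, SD and n per strain × treatment × session, with
undefined values excluded and counted (never imputed); the SD of a
single observation is NA. Pearson correlations are computed on
per-individual mean parameters pooled across groups — the cohort design
observes 15 individuals per group, so the individual is the replicate —
with segment-level correlation available behind `unit = "segment"`.
Hypothesis tests (two-factor ANOVA, multiple comparisons) are deliberately
not reimplemented; the summary tables expose exactly the inputs needed to
run them in standard tools.

# Known limitations

- The slip detector needs per-frame drops above 2 mm; slower, multi-frame
  slides go uncounted. Lowering the threshold toward typical step lengths
  would flood the count with ordinary downward walking.
- The fractal estimator is window-length dependent and grid-anchored;
  values are comparable only within a fixed window and box ladder.
- Pattern labeling assumes k = 9 with a 3/1/3/2 split; other cluster
  counts require a different labeling rule.
- The simulator's treated presets saturate below their nominal slip
  rates (see above); treated-group slip counts are directional, not
  absolute, targets.
```{r session}
sessionInfo()
```
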