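---
title: "Quantifying salt-chemotaxis behavior: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying salt-chemotaxis behavior: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormnav)
```

# Overview

`wormnav` quantifies *C. elegans* gustatory navigation on linear NaCl
gradients, from raw video to per-animal behavioral indices, together with
the physiological readouts that accompany such studies (calcium-trace
normalization and GPCR concentration-response fitting). Every stage can be
exercised on fully synthetic inputs: a run-and-tumble simulator with
controllable navigation biases generates ground-truth trajectories, a
renderer turns them into frame stacks, and closed-form generators produce
calcium traces and dose-response tables. This vignette explains the models,
the fixed thresholds, the places where a convention had to be chosen, and
what the synthetic data can and cannot tell you about real recordings.

# The assay geometry

A linear gradient is an affine map from arena position to NaCl
concentration. `gradient_spec()` stores an origin, a unit axis vector
(the up-gradient direction, `+y` by default, matching a plate poured as a
wedge along one axis), edge concentrations (0 and 100 mM by default over a
120 mm plate) and the release coordinate, which defaults to the midpoint —
the plate center, where animals experience roughly 50 mM. Concentration is
clamped at the plate edges. Positions on the gradient are always reported
as the axis coordinate *relative to the release point*; plates with a
different release offset are expressed through `release_mm`.

# Tracking model

Worms are imaged in trans as dark blobs on a bright arena at 2 frames/s.
The tracker follows the classical centroid pipeline:

1. **Background subtraction.** The background is the per-pixel mean over
   the whole stack; the foreground of a frame is `background - frame`,
   clipped at zero (a `polarity` flag covers bright-on-dark data). A truly
   stationary animal is absorbed into the mean background, so
   `detect_blobs()` also accepts an explicit background image for such
   cases.
2. **Smoothing and thresholding.** The foreground is Gaussian-smoothed
   (EBImage) and binarized at a fixed intensity threshold.
3. **Size gating.** Connected components outside the single-animal area
   range are discarded; two overlapping worms merge into one oversized
   component and simply vanish for those frames, which terminates both
   tracks rather than corrupting them.
4. **Centroids.** The intensity-weighted center of mass of the smoothed
   foreground component, in continuous pixel coordinates. On clean
   rendered blobs this is accurate to well under half a pixel.
5. **Linking.** Greedy nearest-neighbor assignment between adjacent frames
   under a maximum displacement. A track terminates when its detection
   disappears, when two tracks claim one detection (a collision), when two
   candidates are exactly equidistant (ambiguity terminates rather than
   guesses), or when the centroid enters a border margin (about two blob
   radii; the margin is a parameter because plate edges vary). There is
   deliberately **no gap bridging**: a lost animal starts a new track, and
   the analysis layer tolerates multiple tracks per animal downstream.
6. **Preprocessing.** Pixel tracks shorter than 5 min are discarded.
   Coordinates convert to mm, are smoothed with a centered 1.5 s moving
   average (3 samples at 2 Hz), and instantaneous speed is the step
   displacement over the step duration. The half-window at each track end
   is trimmed rather than averaged with a partial window: partial windows
   would bias edge speeds, while trimming keeps the smoother exact on
   constant-velocity paths (a property the test suite asserts to 1e-9).

# Behavioral-state segmentation

Four mutually exclusive per-sample states: `pause`, `turn`, `pirouette`,
`run`. The rules, with their fixed thresholds (`segmentation_params()`):

- **Pause** — speed below 0.01 mm/s for *strictly more than half* of the
  samples in a 10 s window centered on the sample; truncated windows at
  track ends use the available samples. Ties (exactly half) are not
  pauses.
- **Turn core** — the vertex angle at the sample, between the track points
  at least 0.3 mm behind and ahead along the path, is strictly below 80
  degrees. A straight path scores about 180 degrees, a hairpin near 0. The
  0.3 mm lookup takes the first sample at or beyond the arc distance (no
  interpolation), so labels stay sample-aligned; samples whose lookup runs
  off a track end are not evaluable. The angle is measured at the vertex;
  a `complement` convention (angle between successive displacement
  vectors) is available behind a flag for comparison with other codebases.
- **Post-turn extension** — contiguous samples after a turn core with
  speed below 0.1 mm/s belong to the turn. The extension is forward-only:
  the rule claims time points *after* the turn, never before.
- **Pirouette** — turns separated by gaps strictly shorter than 3.8 s
  chain into one pirouette event spanning first start to last end; the gap
  samples are relabeled accordingly. Isolated turns keep kind `turn`.
  Reversals and omega turns are not distinguished; both are turns.
- **Precedence** — turn/pirouette > pause > run. A stationary post-turn
  sample satisfies both the pause and the extension rule; the extension
  rule claims it explicitly, so turns win. Runs are the maximal leftover
  intervals; each run's direction is the sign of its net axis
  displacement (`up`/`down`, with exact zero a `tie` counted for neither).

The test suite re-evaluates every rule with an independent brute-force
oracle (naive per-sample loops, own distance accumulation) on randomized
synthetic tracks and requires exact label agreement.

# Navigation indices

Per animal, over an analysis window (default the first 10 min after
release, requiring at least 5 min of in-window presence, which also keeps
one animal from contributing several short tracks; a 0-300 s preset covers
small-plate assays):

- **Chemotactic index** — mean signed velocity along the gradient axis
  over mean crawling speed. The per-sample signed velocity uses the same
  step convention as speed, so the index is bounded by 1 in magnitude and
  is exactly +1/-1 for straight up/down motion.
- **Biased-random-walk (BRW) index** — `(mu_up - mu_dn)/(mu_up + mu_dn)`
  where `mu` are per-direction mean run *durations* (the run-length
  reading is fixed by the assay's description of relative run durations).
  Runs clipped by the window contribute their in-window duration. A
  direction with no runs contributes mean 0, so a one-sided animal scores
  +/-1; this convention is switchable in principle but is the default
  because it keeps such animals in the sample.
- **Klinotaxis index** — among runs that immediately follow a
  reorientation event and last at least 5 s, the fractional difference of
  those starting up- versus down-gradient, judged by the net axis
  displacement over the first 5 s. Shorter post-reorientation runs are
  discarded.

All three indices negate exactly (to machine precision) when the gradient
axis is reversed; this antisymmetry is asserted on random tracks.

**A known estimator coupling.** The 5 s qualification rule interacts with
run-length bias: when run termination depends on heading, up-gradient runs
are longer and qualify more often, so a pure run-length bias leaks a small
positive klinotaxis reading (about +0.1 at a strong bias) even when
post-reorientation headings are drawn without preference. Symmetrically, a
pure steering bias inflates the BRW index through the one-sided-animal
convention and through reorientations missed by the geometric rule (a
shallow turn merges two runs). These couplings are properties of the
published estimators, not implementation artifacts — they appear with
ground-truth labels too — and the test suite asserts the direction and
subordinate size of the leakage rather than pretending it is zero.

# The run-and-tumble simulator

`simulate_population()` is a discrete-time (0.5 s) state machine per
animal, emulating the two navigation strategies the indices are built to
detect:

- **Runs** at a per-run speed drawn from a truncated normal (default mean
  0.12 mm/s — typical crawling speed on agar — with a small 0.01 mm/s
  within-animal sd), with per-step wrapped-Gaussian heading jitter
  (default 5 degrees).
- **Biased random walk**: per-step termination probability
  `lambda0 * dt * (1 - beta * cos(phi))`, `phi` the angle between heading
  and up-gradient. `beta > 0` lengthens up-gradient runs, which is the
  classic run-length mechanism. `lambda0` defaults to 0.05 1/s (mean run
  about 20 s, the order observed off food).
- **Klinotaxis**: after each reorientation the new heading points into the
  up-gradient half-circle with probability `(1 + kappa)/2`, uniform within
  the chosen half. This is the simplest mechanism the klinotaxis index
  detects while leaving run durations untouched.
- **Reorientations** are stationary turn cores of 1.5 s; with probability
  `pirouette_prob` (default 0.25) a reorientation is a burst of 2-4 turns
  separated by sub-3.8 s gap runs, i.e. a pirouette by construction.
- **Pauses** initiate at a Poisson rate during runs (default 0.005 1/s)
  with exponential durations (mean 12 s, long enough for the 10 s pause
  window to see them); the animal is stationary while pausing.
- **Boundaries** reflect by default; a `truncate` mode ends the trajectory
  at first contact, emulating a tracker that drops animals at the arena
  edge.

Where the source assay does not pin a value (run/pause rates, dwell times,
jitter), the defaults above are order-of-magnitude choices for adult
hermaphrodites crawling on agar, fixed once and exposed as parameters; no
empirical duration distributions are asserted against real data.
Reproducibility follows a counter scheme — worm `i` uses seed
`(seed + i * 10007) mod (2^31 - 1)` — so populations are bitwise
reproducible and invariant to reordering.

**What the generator does not emulate.** Centroid motion only: no body
posture, no omega-versus-reversal distinction, no speed modulation during
turns beyond the stationary core, no lawn or food geometry, no
experience-dependent state. Passing tests on synthetic data therefore
demonstrate that the *computational rules* are implemented exactly and
that the estimators recover imposed biases with the right sign, magnitude
ordering and null calibration — they do not validate biological parameter
values.

# Roaming and dwelling

On-food foraging is classified per 10 s bin in speed versus angular-speed
space. Heading comes from successive displacements of the smoothed path;
angular speed is the absolute wrapped heading change per unit time
(deg/s, with static samples skipped as their heading is undefined). Bins
are non-overlapping, aligned to track start, trailing partial bins
dropped. The separating line is `Speed = Curvature / 450` with speed in
mm/s and angular speed in deg/s — the constant's units are not stated in
the assay literature, so the slope is a parameter; points strictly above
the line are roaming, points on it dwelling (the strict reading of
"above"). Off food, `local_search_summary()` reports state-time fractions
from the segmentation plus mean speed, pause samples included (the
per-individual mean is defined over the whole track).

# Calcium traces and receptor pharmacology

- **dF/F0** — background-corrected fluorescence relative to the mean over
  the 10 s before stimulus onset, in percent. A per-sample background
  stream is reduced to its median (the median background of the entire
  channel stream); the result is invariant under any positive rescaling of
  signal and background. A non-positive baseline is reported as undefined
  with a reason rather than a number.
- **dR/R** — the two-channel emission ratio of a cameleon-type indicator,
  relative to its 10 s pre-stimulus mean. The ratio orientation is
  `YFP/CFP` (the standard FRET convention; the assay literature's phrase
  "ratio between CFP and YFP" is ambiguous), with `ratio_order` exposed.
- **Well normalization** — `ligand/(ligand + lysis)`: the detergent-lysis
  luminescence measures the total releasable calcium response, and the
  series is then scaled to its maximum (100% activation). "Total response"
  could also be read as the lysis integral alone; the adopted reading is
  flagged in the interface. Ligand responses are integrals over the 30 s
  read, not peaks.
- **EC50 fitting** — variable-slope four-parameter logistic on log10
  concentration, all wells as observations (replicate means would discard
  error structure), initialized at the data range with the half-range
  crossing by linear interpolation, solved by Levenberg-Marquardt
  (minpack.lm). Non-convergence, a non-positive Hill slope, or a flat
  response yields a flagged fit with diagnostics instead of a number.
  Noiseless generated curves are recovered to 1e-6 relative; on noisy
  series the 2-SE interval on logEC50 covers the generating value at
  roughly its nominal rate.

# Numerical conventions worth knowing

- Time grids are uniform at 0.5 s; imports are snapped to the grid with a
  warning because every windowed rule assumes uniform sampling.
- Speed attaches to the step *ending* at each sample, with the first
  sample duplicated. Consequently per-sample labels can shift by one
  sample under time reversal; block-level properties are preserved.
- Quartiles interpolate between order statistics (`quantile` type 7), and
  report whiskers follow the Tukey 1.5 x IQR rule — the conventional
  reading of "most extreme points not considered outliers".
- Report generation is deterministic given inputs; all generators are pure
  functions of parameters and seed.

# Problem sizes used in the checks

The packaged checks run populations of 200 animals for 30 simulated
minutes per bias level (null calibration and monotonicity), 50 randomized
5-10 min tracks for the segmentation oracle, a 10-worm 10-min rendered
video at 2 fps for tracker fidelity, and 200 seeded replicates for EC50
coverage — sizes chosen to give the statistical assertions comfortable
power while keeping a full run in the order of a minute of CPU.

# Known limitations

- Identity is not preserved through collisions; the tracker terminates and
  restarts, as the downstream window rule expects.
- The geometric turn rule misses shallow reorientations (heading changes
  under about 100 degrees); this is inherent to the vertex-angle
  definition and is the main source of label disagreement with simulator
  ground truth (about 90-95% agreement in a clean regime).
- Imaging ROI extraction is out of scope: calcium analysis starts from
  per-ROI traces.
- The package computes descriptive statistics only; inferential
  comparisons between conditions are left to standard tools.
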