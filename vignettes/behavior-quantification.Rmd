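---
title: "Quantifying Stentor shape-state behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Stentor shape-state behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stentr)
```

## The behavioral system

*Stentor coeruleus* is a giant (0.5–1 mm) trumpet-shaped ciliate that
alternates between three shape–behavior states in a quasi-2D chamber:

* **droplet** — a contracted sphere, produced by an ultrafast
  whole-body contraction, usually short-lived;
* **cone** — the elongated free-swimming form, moving in nearly
  straight runs at about 1 mm/s;
* **trumpet** — the fully elongated form, either rotating locally on a
  circular path of fixed diameter or anchored to a substrate by its
  posterior holdfast while feeding.

The package quantifies this behavior from time-lapse recordings:
per-frame segmentation yields the cell center and length; kinematics
turns these into smoothed, normalized series; the state field
classifies each frame; transition kinetics are fit with relaxation
models; and spatial statistics describe where the cell spends its time
in structured chambers. A ground-truthed simulator generates recordings
with the same statistical structure, so every stage of the analysis can
be validated against known parameters.

## The state field and classification

Each frame is a point $S_i = (\tilde L_i, \tilde s_i)$ on the
normalized length–speed plane. The normalization reference $(L_0, s_0)$
is the average length and speed over a 10 s window of cone-state free
swimming, so the cone sits at $(1, 1)$. Smoothing uses centered
running medians over $\pm 5$ s computed over valid frames only, which
bridges frames where segmentation failed without interpolating them.

Classification is rule-based: a cell swimming at $\tilde s \ge 0.5$ is
a cone; a slow cell is a droplet if $\tilde L \le 0.8$, a trumpet if
$\tilde L \ge 1.2$, and *transition* in between. The numeric cuts are
inferred from the well-separated per-state distributions of normalized
length and speed (the original classification of such recordings was
manual); they are exposed in `classification_thresholds()`. State
frequencies count only steady labels — transition and invalid frames
are excluded and the three fractions sum to 1.

Two details of the normalization matter in practice:

* **Representative, not fastest, window.** Early cone bouts are still
  elongating from the droplet (the droplet-to-cone relaxation takes
  tens of seconds), so a window chosen purely by maximum speed can land
  on a bout whose length is well below the cone resting length and
  skew every normalized quantity downstream. `normalization_ref()`
  therefore restricts candidates to fast, length-stable 10 s windows
  and picks the one whose mean length is closest to the median length
  over all fast frames. On simulated recordings this reduced the
  between-recording spread of recovered state frequencies by more than
  half.
* **Fixed-override path.** A recording with no usable cone window (a
  cell that adheres throughout) can be normalized with a fixed
  $(L_0, s_0)$ pair via `normalize_track(track, L0 = , s0 = )`.

The transition-vector field is the central difference
$v_i = S_{i+1} - S_{i-1}$, averaged over $\pm 5$ s, gridded at 0.1
normalized units with per-cell component-wise medians; cells holding
less than 0.05% of all points are emptied. Note the intrinsic caveat:
two transitions traversing the same path in opposite directions cancel
toward a zero median. Steady states for clustering are obtained by
masking $\pm 15$ s (droplet), $\pm 60$ s (cone) and $\pm 30$ s
(trumpet) around every label change — each state's margin applies on
its own side of the boundary, a reading we adopt because the margins
are clearly keyed to the states by name — and clustered by
complete-linkage agglomerative clustering on every 10th point, with
clusters matched to states by their centroid geometry.

## Transition kinetics

The deformation rate is $\varepsilon(t) = (L(t) - L_0)/L_0$, with $L_0$
the 10 s pre-transition average for elongations and the contracted
length for the contraction. The three slow elongations follow
$\varepsilon(t) = A\,(1 - e^{-t/\tau})$, with default (measured) time
constants 16.2 s (droplet→cone), 40.1 s (droplet→trumpet) and 107.9 s
(cone→trumpet). The trumpet→droplet contraction is more than four
orders of magnitude faster and follows the two-mode decay
$\varepsilon(t) = B_1 e^{-t/\tau_1} + B_2 e^{-t/\tau_2}$ (defaults
$\tau_1 = 2.1$ ms, $\tau_2 = 15.6$ ms, reported with
$\tau_1 < \tau_2$), the solution form of a damped mechanical
relaxation; `fit_contraction()` also fits the single-mode model and
reports both residual norms so the two-time-scale comparison is
explicit, refitting from the nested solution if the optimizer ever
leaves the two-mode fit above the single-mode one.

Start detection uses the line-crossing construction for elongations
(plateau line over the 10 s before the candidate rise, rise line over
the first 30 s, candidate triggered by 3 plateau-residual SDs for 3
consecutive frames) and the post-contraction length minimum within
20 s for regrowth. Because a hard truncation at a misplaced start
biases $\tau$ substantially (we measured +50% on noiseless
cone→trumpet traces when the start came from the line crossing alone),
`fit_elongation()` instead fits a free onset $t_0$ —
$\varepsilon(t) = A(1 - e^{-(t - t_0)/\tau})$ for $t \ge t_0$, zero
before — initialized at the detected crossing. Noiseless round-trips
then recover $\tau$ to well beyond four significant digits, and the
crossing detector is still exposed and tested on its own.

All nonlinear fits use Levenberg–Marquardt least squares with
deterministic initialization (amplitude from the trace plateau, $\tau$
from the time to 63% of it, contraction modes split evenly with
$(\tau_1, \tau_2)$ started at (1, 10) ms) and positivity bounds, so
fits are seed-free and reproducible. Amplitudes are bounded positive;
whether the original fits constrained them is not stated, and the
choice only matters for degenerate traces, which are rejected anyway.

During the cone→trumpet switch, speed and length are normalized so the
maximum speed is 1 and the length at that moment is 1, and speed is
regressed on length (log–log OLS) in the two fixed normalized-length
ranges 1–1.25 and 1.25–1.45; the breakpoint is fixed at 1.25, not
estimated. The series entering the fit are the ±5 s median-smoothed
ones, consistent with the rest of the chain; this matters because
additive length noise otherwise attenuates the steep lower-range
exponent (classical errors-in-variables dilution: about −5.9 instead
of −6.3 at noise SD 0.02 on raw series).

Rotation laps are delimited by the winding number: a lap ends when the
net (signed) cumulative heading change of the displacement direction
reaches $2\pi$. We use the *net* sum deliberately — unsigned cumulative
heading change grows without bound under measurement jitter (laps were
cut an order of magnitude too early at 0.05 mm positional noise),
while jitter cancels from the net winding and both definitions agree
for consistent rotation. The lap diameter is the maximum pairwise
distance among the lap's positions.

## The behavior simulator

`simulate_behavior()` generates ground-truthed recordings from a
semi-Markov state process with motion and length dynamics layered on
top:

* **States and transitions.** The embedded chain forbids the
  cone→droplet contraction (essentially never observed): droplets
  elongate into cones with probability 0.93, otherwise directly into
  trumpets; cones switch to rotating trumpets at rate
  $1/\text{dwell}_C$ in competition with a position-dependent adhesion
  hazard; every trumpet eventually contracts back to a droplet.
* **Dwell times** are gamma-distributed with shape 3 (`dwell_shape`;
  shape 1 restores exponential dwells). Behavioral bout durations are
  generally better described by unimodal, non-exponential
  distributions, and exponential dwells make single-recording state
  frequencies so variable (SD ≈ 4 percentage points across seeds even
  for 12 h of simulated behavior) that no desk-scale recording could
  pin them down; with shape 3 the analytic stationary occupancy is
  unchanged (it depends only on visit rates and mean dwells) while
  frequencies stabilize to ±1–2 points.
* **Length** relaxes in closed form toward the current state's target
  (droplet 0.25, cone 0.5, trumpet 0.75 mm — scale-free ratios
  0.5 : 1 : 1.5) with the transition-specific $\tau$; the contraction
  uses the two-mode decay in milliseconds.
* **Motion.** Cones swim straight at 1 mm/s with small heading
  diffusion and specular reflection at walls (the simplest
  confinement-preserving choice). Non-adhered trumpets spiral onto and
  orbit a circle of diameter 1.4 mm placed in the nearest feasible
  position, moving at the speed given by the piecewise power-law
  coupling $s \propto l^{-6.3}$ (normalized length 1–1.25) then
  $s \propto l^{0.2}$ (above 1.25), so the scaling analysis has exact
  recoverable ground truth. Droplets and adhered trumpets are
  stationary. Trumpets entered directly from the droplet state remain
  stationary until they reach trumpet-like length, then orbit.
* **Adhesion** is a hazard on swimming cones, multiplied by
  `crescent_adhesion_multiplier` while the cell is inside a crescent
  dead-end area. The anterior direction of an adhered cell points away
  from the dead end (toward the chamber center from the nearest
  crescent tip) with a wrapped-normal spread set by
  `anterior_concentration`. Ground-truth events (start, duration,
  position, angle, crescent flag) are recorded.
* **Randomness** flows from the single integer seed; observation noise
  draws from a derived sub-stream so that changing noise levels leaves
  the state and motion sequence untouched. Identical inputs give
  identical recordings.

### Calibration of the free parameters

The source recordings report state *frequencies*, not switching rates,
so the dwell means are calibrated, not measured. The defaults were
tuned once by long-run simulation so that the full analysis chain
(smoothing, normalization, classification) recovers the observed
frequencies — droplet 2.0%, cone 72.3%, trumpet 25.7% in the plain
chamber — giving dwell means of 1.9 s (droplet), 50 s (cone), 86 s
(rotating trumpet) and 240 s (adhered trumpet) with a baseline
adhesion hazard of 1/4000 s⁻¹. The nominal droplet dwell is short
because the observed droplet fraction largely consists of early
elongation frames that still look droplet-like; classified and true
occupancies differ systematically wherever the ~1 min cone→trumpet
elongation overlaps the classification cuts, and the calibration
targets what the pipeline measures, as the original frequencies were
themselves measurements.

The structured chamber (5 mm outer disk, 2.5 mm inner disk offset to
leave a 0.1 mm closest-approach gap) uses
`structured_behavior_params()`: confinement between the disk and the
wall keeps the cell in near-constant surface contact, which strongly
promotes holdfast anchoring, so the baseline hazard rises to 1/60 s⁻¹
with the crescent multiplier (20) still concentrating adhesion in the
dead ends; adhered dwells average 250 s. This calibration reproduces
the structured-chamber trumpet fraction (72.4%); the recovered cone
and droplet fractions (about 25% and 3%) sit farther from the
observed 16.9% and 10.7% — the single-cell model has no mechanism
that prolongs droplets specifically in structured chambers, a known
limitation.

Crescent tips are computed as the two points on the channel mid-curve
where the wall–disk channel narrows to one cell width (0.2 mm) — one
concrete reading of "the tip of the crescent"; crescent areas are the
free-area points within 1 mm of either tip.

## The movie renderer and segmentation

`render_frames()` draws 16-bit grayscale frames: a background field
(optionally with a static slow gradient), i.i.d. Gaussian pixel noise,
a dark teardrop of major axis equal to the true length at the true
position and motion-derived heading, and optional static dust. Frames
at 0.04 mm/px over a 6 mm field (150×150 px) keep long movies
tractable; the renderer refuses scales that would make the cell
shorter than 3 px.

Segmentation follows the recording-analysis chain: per-pixel median
backgrounds over ~400 s sections for single-cell movies (maximum
backgrounds over 15 min, triangle threshold, 0.5 px blur and 1°
polar step for chamber-survey movies), absolute background
subtraction, Gaussian blur, maximum-entropy (Kapur) or triangle
thresholding of the 8-bit histogram, optional 4 px opening, a
circularity filter ($4\pi A/P^2 \ge 0.3$; the filter is documented for
the original analysis but its value is not, and 0.3 separates
elongated cells from debris comfortably), and selection of the largest
surviving connected component. Two guards added for unattended
operation: a minimum component area, and a prominence test (component
mean difference ≥ 25× the image's median absolute difference) that
flags cell-free frames invalid instead of segmenting noise clumps —
correlated blurred noise reaches prominence ratios around 15, real
cells sit far above 60. Invalid frames are bridged downstream by the
valid-only medians. For long movies `segment_stack()` can restrict the
search to a window around the last valid position (standard
single-particle tracking practice) with automatic full-frame fallback.

One systematic effect deserves mention: on synthetic renders the
maximum-entropy threshold lands near the noise floor of the
difference-image histogram, so the mask keeps part of the ~2 px blur
skirt and the measured length overshoots the drawn length by a
roughly constant ~2 px per end. Because every downstream quantity is
normalized to the cone state ($\tilde L = L'/L_0$), this dilation
cancels to first order and classification margins remain wide; it
does mean raw mask areas run ~20% above drawn areas even at fine
resolution.

The cell length is the sum of the top two local maxima of the radial
profile $l(\theta)$ (distance from the centroid to the farthest
foreground pixel per ray, 2° steps), with the second maximum required
to lie at least 90° from the first so that the anterior and posterior
ends — near-opposite on an elongated cell — are used rather than two
samples of one end.

## Spatial statistics

Occupancy density maps count cell centers on a 56×56 grid over a
6×6 mm field centered on the chamber and normalize so the density
integrates to exactly 1 (asserted to 1e-9); corner cells outside the
chamber legitimately hold zero. Presence frequency is non-adhered
residence time per unit region area (s/mm²). Adhesion events are
detected automatically as maximal intervals during which the center
stays within 0.2 mm (about one cell width) of a fixed point — a
running bounding-box criterion whose half-diagonal bound guarantees
the stay radius — and events shorter than 10 s are not counted.
Group comparisons use Welch's *t*-test, computable both from raw
samples and from printed summaries (mean, SE or SD, n) with
Welch–Satterthwaite degrees of freedom, which reproduces published
p-values from published summary tables.

## Problem sizes and runtimes

The shipped defaults are desk-scale choices: kinetics validation uses
20 noisy traces per transition kind (10 fps elongations, 2000 fps
contraction), the scaling analysis 10 transitions, lap statistics
about 170 laps from ten 300 s rotating recordings, and the
occupancy analyses 8 h of simulated behavior per chamber rendered at
2 fps (57,600 frames, a few minutes of wall time each). With the
calibrated generator these sizes put the frequency estimates within
1–2 percentage points (SD across seeds) of their targets.

## What passing tests do and do not show

The simulator reproduces the statistical structure the analysis
assumes — three states with calibrated frequencies, relaxation
kinetics with the measured time constants, the speed–length scaling,
fixed-diameter rotation, geometry-biased adhesion — but not the full
texture of real recordings: no hydrodynamics or ciliary beating, no
feeding currents, no photoresponse, no cell-to-cell variability in
targets or speeds, simplified wall interactions (specular reflection),
and rendered cells are smooth teardrops rather than textured bodies
with a visible membranellar band. Passing the acceptance suite
therefore demonstrates that the *analysis chain* is correct and
unbiased at realistic noise levels, not that the simulator is a
faithful digital twin of the organism.
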