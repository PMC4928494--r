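---
title: "Modeling free viewing as a biased correlated random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling free viewing as a biased correlated random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazewalk)
```

## The model

`gazewalk` treats free viewing of a complex scene as appetitive foraging:
the eyes forage for bottom-up salience, a crude surrogate for visual
information. The walker alternates saccades and fixations at a 5 ms
resolution (matching a 200 Hz eye tracker). At every step the movement
direction is a compromise between inertia and attraction,

$$\theta_t \;=\; \arg\!\big[\,p\,\hat u(\theta_{t-1}) + (1-p)\,\hat u(\phi_t)\,\big],$$

where $\hat u(\cdot)$ is a unit vector, $p$ is the *persistence* (the
empirical probability that the gaze direction changed by no more than 45°
between successive samples, a function of warped time within the event),
and $\phi_t$ is the *bias direction*: the direction of steepest ascent of
the current salience map for the BCRW, or an i.i.d. uniform random direction
for the CRW control. Speeds are drawn per step from empirical velocity
distributions; durations and saccade departure angles are drawn from their
pooled empirical distributions. Nothing else is fitted: the walker is a
piecewise re-sampler of observed oculomotor statistics, steered by the map.

A fixation's location is the mean position over its last 25 ms (absorbing
jitter and the slow drift toward local salience peaks that the gradient
ascent produces). Completing a fixation *consumes* the salience within the
inhibition-of-return (IOR) radius — it is set to exactly 0 — and the
consumed values are restored, bit for bit, after $1/\tau_{IOR}$ subsequent
fixations. Consumption models extraction of information at a fixated spot;
recovery models its replenishment.

Key modeling assumptions, inherited knowingly:

* salience is purely bottom-up and static over the trial;
* event durations are i.i.d. draws — ordinal-position trends and
  correlations between successive fixation durations and saccade amplitudes
  are deliberately not modeled;
* persistence and velocity depend on warped within-event time only;
* the walk starts at the image center (the trial-initiating fixation cross).

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dt_ms` | 5 | ms | tracker acquisition rate (200 Hz) |
| `total_time_ms` | 10 000 | ms | viewing period per trial |
| `smoothing_sigma_dva` | 0.5 | dva | smooths the map so gradient ascent can climb peaks |
| `border_buffer_dva` | 1 | dva | reflect the walk away from the border |
| `border_saccade_distance_dva` | 2 | dva | re-entry displacement after leaving the image |
| `ior_radius_dva` | 2 | dva | consumed disk around a fixation |
| `ior_tau` | 1/17 | per fixation | salience recovers after 17 later fixations |
| `fixation_loc_window_ms` | 25 | ms | fixation location = mean of the last 5 steps |
| `n_runs` | 100 | — | ensemble size for a fixation-PDF prediction |
| `px_per_dva` | 25 | px/dva | default image geometry (600×800 px ≙ 24×32 dva); the shift-task geometry (378×756 px, 16×32 dva) gives 23.625, so this is per-dataset, not a constant |

The four border/IOR values are the best-fit cells of the documented
parameter sweep; `sweep_grid()` re-exposes the full grids (border buffer
{0.04, 0.4, 1, 2, 4} dva; border saccade distance {0.4, 1, 2, 4, 8} dva;
τ_IOR {0, 1/50, 1/35, 1/25, 1/17, 1/12, 1/7, 1/3, 1}; IOR radius
{0, 1, 2, 4} dva) and `bcrw_parameter_sweep()` scores them by KL divergence
with 10 runs per cell, one parameter varied at a time.

## The salience front end

The map is the classic center–surround architecture: a 9-level dyadic
Gaussian pyramid; intensity, broadly tuned color opponency (RG, BY,
luminance-normalized where intensity exceeds a tenth of its maximum) and
Gabor-energy orientation channels (0°, 45°, 90°, 135°, quadrature pair,
zero-DC); center scales {2,3,4} against surrounds {c+3, c+4}; per-map
normalization that scales to [0, 1] and multiplies by
$(1-\bar m)^2$ with $\bar m$ the mean of the non-global local maxima
(promoting maps with one dominant peak); equal-weight conspicuity
combination at level 4; upsampling; min–max normalization. Images smaller
than 64 px on a side are rejected (the coarsest scales degenerate).
Exact salience values are implementation-specific across the literature —
only the map's qualitative structure (where the peaks are) is contractual,
and that is what the tests pin down.

## What the synthetic generators emulate

`make_scanpath()` emulates a tracked scan path: lognormal fixation
(mean 215 ms, sd 90 ms) and saccade (mean 56 ms, sd 12 ms) durations
truncated at the 25/10 ms detector minimums, isotropic Gaussian fixation
jitter (sd 0.1 dva), straight saccades with a symmetric raised-cosine speed
profile, and occasional held direction kinks (complement of
`persistence_saccade`, default 0.9) so saccade persistence stays below 1
but above fixation persistence (~0.25, the analytic value for i.i.d.
uniform directions). `make_scene()` renders gray backgrounds with colored,
soft-edged blobs; `decouple_intensity = TRUE` makes the blobs isoluminant
(zero-mean opponent perturbations) and adds a broad bright patch away from
them, so salience and brightness make opposed predictions — the
configuration under which the model ordering (BCRW > salience > intensity)
is decidable at all.

What passing tests do **not** show about real data: the generators contain
no semantic content, no photographer's bias, no ordinal trends, no
saccade-amplitude/duration coupling (targets are fixed waypoints), and no
tracker drift or blinks. Recovery of the generator's distributions is a
closure property of the pipeline, not evidence about monkeys.

## Numerical choices

* **Direction combination** is done on unit vectors, not raw angles
  (averaging angles is discontinuous at ±180°); a zero resultant
  (antipodal directions at weight ½) keeps the previous direction.
* **Zero salience vs. undefined gradient.** "Salience is zero" is an exact
  test (IOR writes exact zeros). During a saccade the walk then keeps its
  heading; during a fixation the bias becomes a random draw from the
  departure-angle distribution. A *nonzero but flat* region (zero gradient,
  e.g. a constant map) falls back to the same rules, which makes the BCRW
  on a featureless map degenerate to CRW-like behavior.
* **IOR bookkeeping** uses pixel ownership: a pixel is recorded by the
  fixation that zeroed it while nonzero; a later overlapping fixation takes
  the record over. This keeps three properties simultaneously: the full
  disk is zero after any fixation, an entry restores exactly its pixels
  after 17 later fixations, and `current` plus the ledger reconstructs the
  smoothed base map exactly at every step. The gradient is recomputed
  locally (affected disk + 1 px) after every IOR update by default;
  `recompute_gradient = FALSE` keeps the initial field for users who prefer
  the map-at-t0 reading, since either is defensible.
* **Constant images** have undefined min–max normalization; their maps are
  defined as all zeros (with a warning), and numerically constant maps
  (relative range below 1e-9) are treated the same so FFT round-off noise
  is never amplified into a fake map.
* **Binning** uses half-open 1×1 dva bins anchored at the top-left pixel;
  a partial last bin absorbs remainder pixels (relevant for the 23.625
  px/dva shift-task geometry). Empty bins are floored at 2⁻⁵² before
  normalization so KL divergence is always finite.
* **KL divergence** is reported in bits (log base 2) by default, matching
  how such divergences are usually quoted; the base is an argument because
  the natural-log convention is equally common.
* **AUROC** uses midranks, so ties (e.g. many fixations in one PDF bin)
  score 0.5 per tied pair, and the statistic is invariant under strictly
  monotone transformations of the map.
* **Event minimums** are enforced by absorbing sub-threshold runs into
  their flanking label, shortest first, until the labeling is admissible —
  a 20 ms stationary pause between two saccades merges into the saccade
  rather than becoming an illegal fixation. A path with no movement at all
  is one fixation by definition (k-means is undefined on identical points).
* **Event completion at time-out:** the event in progress when the 10 s
  budget expires is completed rather than truncated, so paths slightly
  overshoot 10 s; every path therefore spans *at least* the configured
  duration.

## Problem sizes

The test suite and the acceptance script use 300×400 px (12×16 dva) scenes,
a 5-recording × 30-event synthetic corpus for the behavior profile,
20-run BCRW ensembles against 5-run "observed" sets over 10 decoupled
scenes, a 145-run CRW ensemble (≥ 5000 fixations) for the uniformity check,
and 500+ events for profile recovery. These sizes give stable orderings and
tight (≤ a few percent) statistics while keeping a full run in minutes;
ensembles of 100 runs on 600×800 px images behave identically, only slower.

## Known limitations

Simulated saccades curve toward salient regions more than real saccades do;
the persistence term alone does not enforce main-sequence kinematics.
Ensemble averaging hides this, and the fixation *locations* — the quantity
the model predicts — are insensitive to within-saccade trajectory shape.
The salience front end is one parameterization of a family; supplying any
externally computed map of matching geometry to `simulate_bcrw()` is
supported and encouraged. The event classifier is contract-tested on
synthetic ground truth, not against any reference implementation; on real
data its k-means state-space split should be checked per dataset.
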