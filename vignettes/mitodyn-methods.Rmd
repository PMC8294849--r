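---
title: "Quantifying mitochondrial dynamics in PV+ interneurons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial dynamics in PV+ interneurons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

Parvalbumin-positive (PV+) interneurons are fast-spiking GABAergic cells
with unusually high mitochondrial content, reflecting the energetic cost
of sustained high-frequency firing and perisomatic inhibition. Disrupting
Miro1 (Rhot1), the outer-membrane adaptor that couples mitochondria to
microtubule motors, alters where mitochondria sit in these cells — and,
downstream, axonal arborization, hippocampal gamma oscillations and
anxiety-related behavior. Studying that chain quantitatively requires a
series of small, bespoke measurements: track-level trafficking
statistics, SWC morphometry, shell-binned mitochondrial distributions,
punctum scoring in two-channel images, gamma-band spectral summaries, PSC
event detection, and behavioral scoring. `mitodyn` implements each of
these as a tested, parameterized function, together with generators that
synthesize every input with known ground truth.

This vignette documents the models behind each estimator, the parameters
that matter, and the design decisions taken where the procedures are
conventionally under-specified.

## Trafficking: the 2 um / 300 s rule and pause-excluding velocity

A mitochondrion tracked at one frame per 5 s is **mobile** if its
cumulative path length exceeds 2 um within some contiguous 300-s window
(`classify_mobility()`). Two choices deserve note:

* **Path, not net displacement.** Mitochondria reverse direction;
  particle trackers report path statistics. "Distance covered" is
  therefore the sum of frame-to-frame Euclidean steps.
* **Sliding window.** Movies are 500 s but the rule is stated per 5 min,
  so the rule is evaluated at every window start; tracks shorter than the
  window use a pro-rated threshold (`threshold * duration / window`),
  with a flag to disable pro-rating.

`track_velocity()` computes path length over time after removing
**pauses**: maximal runs of frames with step below an immobility
threshold whose total duration exceeds 10 s (strictly — a 10-s stop is
kept). The immobility step threshold is not part of the published
procedure; the default of 0.1 um/frame sits below the localization
jitter of two-photon tracking at these magnifications and is exposed as
a parameter. Excluding pauses can only raise the velocity relative to
the naive path/duration ratio, which the test suite asserts as an
invariant. When every frame is excluded the velocity is reported as `NA`
— undefined, deliberately distinct from zero.

The track generator (`gen_tracks()`) makes these rules decidable by
construction: mobile tracks move at a constant ground-truth speed
(default 0.17 um/s, a realistic median for these cells) with optional
whole-frame pauses; immobile tracks jitter with per-frame steps drawn
from U(0, 0.03) um. The jitter bound is chosen so that even the maximal
jitter path (60 frames x 0.03 um = 1.8 um) stays strictly under the
2-um threshold in every 300-s window; requests that cannot satisfy the
rule (e.g. speed x window below threshold) raise a parameter error
rather than emitting unclassifiable tracks.

## Morphometry: SWC trees, Sholl analysis, and the volume mask

Reconstructions are standard 7-column SWC trees (soma = 1, axon = 2,
dendrite = 3), validated on read: one root, parents before children,
known type codes, no orphans. On this structure:

* `branch_points()` — non-soma nodes with at least two children. A node
  with three children counts once (branch points, not bifurcations, are
  counted).
* `count_processes()` — edges of the condensed tree whose vertices are
  the root, branching nodes and tips; equivalently, maximal unbranched
  segments.
* `total_length()` — parent-child edge lengths, with each edge assigned
  to its child's compartment so axonal and dendritic totals add up.
* `sholl_intersections()` — crossings between edges and concentric
  spheres centered on the soma root (the single well-defined point in an
  SWC file). Crossings are counted analytically as simple roots of the
  per-segment quadratic, so an edge that dips in and out of a sphere
  counts twice and tangencies count zero; the tests verify this against
  a dense-resampling oracle at 0.01 um.

For mitochondrial distribution analysis, `fill_volume_mask()` rasterizes
the reconstruction into a binary stack as a union of capsules (linearly
interpolated radii along each edge, plus a sphere per node). Degenerate
radii are clamped to half the voxel diagonal rather than half the edge
length: a mask voxel is defined by its center, and the smaller clamp can
leave a thin neurite passing between voxel centers with no mask at all.

`mito_sholl()` reproduces the MitoSholl pipeline: per-slice rolling-ball
background subtraction, median filter, binarization, logical AND with
the volume mask (restricting signal to the filled cell), and binning of
positive voxel centers into half-open 1-um shells `[k, k+1)` from the
soma. Summed over all shells the profile equals the total positive
masked voxel count — a conservation law the tests assert. The published
pipeline used Fiji's "Default" threshold; because that method is only
loosely specified, the package defaults to Otsu and exposes
`threshold = "fixed"` with an explicit value as the alternative, and
counts binary voxels rather than summed intensities.

`min_branch_mito_distance()` is an exhaustive scan: for each branch
point, the minimum Euclidean distance (anisotropic voxel sizes honored)
to any positive voxel center. Ties in "the first pixel encountered" only
affect which voxel is nearest, never the distance, so the scan resolves
them by linear index order. Distances are compared across genotypes
after dividing by the reference group's mean
(`normalize_distances()`), which pins the reference mean at exactly 1,
and summarized as the fraction of branch points with a mitochondrion
within 1 um (`prob_within_radius()`).

## Image quantification

`rolling_ball_subtract()` implements background subtraction as grayscale
morphological opening with a flat disc of the stated radius — the
standard structuring-element formulation of the rolling-ball algorithm.
A flat image maps to zeros, features smaller than the disc keep their
height, and the output is non-negative.

Soma analyses operate on masks: `soma_mito_area_fraction()` is the
percentage of soma pixels that are mitochondria-positive, and
`detect_soma_cluster()` scores a soma as "clustered" when the largest
connected mitochondrial component holds at least half (configurable) of
the in-soma mitochondrial area. The dominance criterion formalizes a
judgment the original analysis made by eye; 0.5 cleanly separates one
perinuclear aggregate from scattered puncta.

Boutons are detected (`detect_puncta()`) as connected components of the
thresholded biocytin channel with calibrated areas inside 0.2-3.0 um^2 —
typical PV bouton sizes; merged blobs above the bound are excluded. A
bouton "contains" mitochondria (`bouton_mito_content()`) when its mean
intensity in the mitochondrial channel exceeds the axon-shaft background
mean plus two standard deviations. This criterion replaces visual
scoring with a reproducible surrogate; on noise-free synthetic renders
it reproduces the generator's ground-truth flags exactly, which is how
the tests pin it down.

`synapse_colocalization()` reimplements object-level pre/post synaptic
marker colocalization: per channel rolling-ball (radius 7), maximum
filter (radius 1), Otsu threshold, connected components; a pre/post pair
is colocalized when the overlap area is 33-100% of the *smaller*
object's area. Many-to-many candidates are reduced greedily to
one-to-one pairs by descending overlap, so the pair count can never
exceed either object count.

## Electrophysiology

**Spectra.** `power_spectrum()` computes the normalized
magnitude-squared FFT of a 300-s analysis window. The default estimator
is Welch's method with 2-s Hann segments and 50% overlap (0.5 Hz
resolution), which stabilizes the peak statistics; `method =
"single_fft"` reproduces the one-shot transform. "Normalized" is pinned
to a testable convention: power summed over all bins equals the signal
variance (Parseval). Bins in 49-51 Hz are flagged and ignored by every
band statistic, excluding the 50 Hz mains. `gamma_metrics()` reports the
in-band (20-80 Hz) peak power, its frequency, and the trapezoidal power
area; `spectrum_width50()` fits `baseline + a *
exp(-(f-mu)^2/(2*sigma^2))` by Levenberg-Marquardt and reports the full
width at half maximum `2.355 * sigma` in Hz (the published width values
carry no unit; Hz is the natural one). A non-converging fit raises an
error instead of returning a number.

**PSC detection.** `detect_pscs()` low-pass filters at 1 kHz
(zero-phase 4th-order Butterworth — the published cutoff, with the
filter family chosen here), subtracts the median baseline, rectifies
into the stated polarity and takes suprathreshold (3 pA) runs as
candidates. Within a run, superimposed events are split at local maxima
whose rise from the preceding valley clears the amplitude floor;
without that rule, ripple on decay tails is double-counted. Events
below `5 x SD(noise)` are then discarded. The noise SD is the robust
`1.4826 x MAD` of the **raw** baseline-subtracted trace outside event
windows: the exclusion rule is meant to reflect the recording's noise,
and estimating it after the low-pass filter would shrink it several-fold
and admit events the rule is supposed to reject. Every returned
amplitude therefore satisfies both floors, which is asserted on every
output.

**Other measurements.** `train_recovery()` normalizes probe responses to
each train's first peak and averages the percentages across trains
(undetectable first peaks exclude that train with a warning).
`intrinsic_properties()` estimates input resistance from the
steady-state I-V slope of hyperpolarizing steps, the membrane time
constant from a single-exponential onset fit, spike threshold at a
dV/dt criterion of 20 V/s (a conventional value; the published
procedure does not state one), AP amplitude and half-width from
threshold to peak, rheobase as the smallest spiking step and the spike
rate at rheobase + 40 pA. `fepsp_slope()` blanks the stimulus artifact
and fits a line over the 20-80% span of the initial response phase;
the synthetic alpha-function generator provides a closed-form chord to
test against.

## Behavior

`zone_occupancy()` assigns each trajectory frame to a named zone by
boundary-inclusive point-in-polygon (points on an arm/center boundary
count as inside, so no frame is lost at junctions; zones must not
overlap, so no frame is counted twice). The built-in elevated-plus-maze
template uses four 30 x 5 cm arms and a 5 x 5 cm junction square — the
published apparatus gives the arm dimensions; the center square is taken
equal to the arm width, the only size consistent with four flush arms.
`rotarod_rpm()` evaluates the accelerating-rod formula `(end - start) /
300 * seconds_run + start`, and `alternation_score()` computes percent
alternation over consecutive valid T-maze choices, flagging animals with
more than 3 NO-GO trials for exclusion.

## The synthetic-data module: what it does and does not emulate

Every generator is a pure function of its parameters and a seed, and
returns ground truth alongside the data. Defaults encode the study's
acquisition settings: 5-s frame interval over 500 s for tracking, 5 kHz
LFP sampling with 300-s analysis windows, 10 kHz voltage clamp, 1-um
Sholl shells, gamma band 20-80 Hz.

The generators emulate the *statistical structure* the estimators rely
on — constant-speed runs with pauses, branching trees with labeled
compartments, Gaussian mitochondrial puncta at 10x background on a
constant baseline, a sinusoid plus white noise for the LFP,
difference-of-exponential PSCs, zone-structured positions — and none of
the nuisance structure of real data: no photobleaching, optical
anisotropy or shot noise, no tortuous neurite geometry, no 1/f LFP
background or non-stationary oscillations, no dendritic filtering of
PSC kinetics, no autocorrelated animal movement. Passing tests
therefore demonstrate that the estimators implement their definitions
correctly and recover known parameters under the stated noise models —
not that those definitions are robust to every artifact of real
microscopy or electrophysiology.

Fractional targets are realized exactly by rounding half away from zero
and assigning any remainder to the lowest-index items, so a requested
23% mobile fraction of 100 tracks is 23 tracks, not a random draw.

## Numerical choices and degenerate inputs

* Shells and windows are half-open (`[k, k+1)`), sphere crossings are
  strict sign changes, and the immobility comparison `step < threshold`
  uses a relative epsilon of 1e-9 so coordinate round-trips cannot flip
  frames at the boundary.
* Otsu thresholds are computed on the data rescaled to `[0, 1]` at 256
  levels; constant images binarize to all-background.
* Undefined quantities are signaled, never defaulted: all-paused tracks
  give `NA` velocity, empty mitochondrial stacks raise an
  undefined-distance condition, non-converging Gaussian fits raise a fit
  error, spike-free sweep families flag rheobase as undefined.
* `run_pipeline()` echoes every effective parameter into its JSON run
  report, so no default is hidden from the record.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
100-track movies, trees with up to ~10 branch points rasterized at
0.4-1 um voxels (10^5-10^6 voxels), 300-s LFPs at 5 kHz, 5-20 s
voltage-clamp traces at 10 kHz, and 100-seed repetitions for the
stochastic detector properties. These sizes keep every oracle
(dense resampling, exhaustive scans, brute-force window maxima)
affordable while matching the acquisition parameters of the study.

## Known limitations

* The trafficking module consumes tracks; it does not detect or link
  particles in raw movies, and no kymographs are rendered.
* Sholl analysis uses the soma root node as the center; reconstructions
  whose root is displaced from the anatomical soma center will shift
  profiles accordingly.
* The COX-IV-style intensity measurements are reported on the native
  intensity scale of the input image; no inter-image normalization is
  attempted.
* ROUT-style outlier removal is not implemented; group-level hypothesis
  tests are left to standard R routines (`wilcox.test`, `t.test`,
  `aov`).
* The EPM/open-field zone templates are idealized rectangles;
  video-tracking artifacts (reflections, occlusions) are upstream of
  this package.
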