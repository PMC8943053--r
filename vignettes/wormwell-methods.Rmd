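---
title: "Methods: multiwell worm tracking, photoresponse and fingerprint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiwell worm tracking, photoresponse and fingerprint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wormwell)
```

`wormwell` implements the analysis stack for high-resolution brightfield
imaging of *C. elegans* in square-well 96-well plates viewed by an array of
cameras, where each camera sees a 4x4 block of wells. This vignette is the
package's account of the models and procedures it implements, the tunable
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the design was genuinely open.
Every empirical claim below is one that the package's test suite or
acceptance script computes itself.

## The imaging geometry and its design arithmetic

A standard 96-well plate imaged at a target resolution of 75 px/mm needs
8100 x 5400 pixels (about 44 megapixels at 3:2), more than any single
25 fps camera provides; an array of six 12-megapixel cameras covers the
plate with 16 square wells per camera at 12.4 um/px (80.6 px/mm), and five
identical units record 480 wells simultaneously. Six 8-bit cameras at
25 fps produce about 6.5 TB of raw video per hour, which is why masked
(background-zeroed) video is the working representation. These are pure
arithmetic and are exposed as the `design_*()` functions so the assumptions
stay testable.

## The synthetic plate simulator

All validation runs on synthetic sessions with complete ground truth,
generated by `simulate_session()`:

* **Scene.** Bright well interiors (intensity 1) on a darker wall/shadow
  band (`wall_dark_frac`, default 0.5), the lattice parameterised by
  offsets and pitches (defaults: 160 px pitch, 130 px inner square,
  matching an 8 mm well at 12.4 um/px). Coordinates are 0-based pixels,
  origin top-left, y down; well boxes are half-open, so a point on a wall
  band belongs to no well.
* **Worms.** Dark sinusoidal tubes (default body length 80 px ~ 1 mm,
  width 6 px, undulation amplitude 6 px, wavelength 55 px) whose chord
  length is corrected for the arc-length elongation of the sinusoid. The
  paper-scale assay places 3 worms per well; initial positions are spread
  out so bodies do not start overlapping, but worms do cross and merge
  during a session, as real ones do.
* **Motion model.** A per-frame three-state Markov chain over
  forward/backward/stationary. The default matrix at 25 fps gives forward
  bouts and pauses of order ten seconds and brief, rare reversals
  (stationary distribution approximately 0.52/0.04/0.45). Blue light
  multiplies the transition probabilities *into* the forward state by
  `light_bias` (default 4) during light-on intervals and renormalises
  rows; this gives closed-form expected mode fractions for calibration
  tests. The chain definition is per frame, so changing `frame_rate`
  rescales the dynamics in real time while leaving the stationary
  distribution unchanged — calibration studies exploit this to run at
  reduced frame rates.
* **Confinement.** The worm *centre* is confined to the well's inner
  square inset by the undulation amplitude plus half the body width;
  moving worms are steered smoothly back towards the well centre when they
  approach the boundary, so bodies never flip instantaneously (which would
  break the head/tail convention) but may transiently overhang the wall
  band, as real worms climbing walls do.
* **Debris.** Static dark blobs, straight scratches and arc-shaped
  crescents, with contrast in the segmentable range, so the non-worm
  filter is actually exercised by the tracker's own detections.

What the simulator does **not** emulate: lens distortion and vignetting,
the 850 nm illumination physics, focus drift, worm self-occlusion in 3D,
body-shape changes (omega turns, coiling), and the real binary imgstore
chunk format (frames are PNG files plus `index.csv`/`metadata.yaml`).
Passing the synthetic acceptance checks therefore demonstrates that the
algorithms are implemented correctly and are calibrated on data obeying
their assumptions — not that they reach any particular accuracy on real
video.

Determinism is a hard contract: the same seed gives byte-identical frame
stores, fixtures and fitted grids.

## Well detection

The well lattice in a field of view is found exactly as a template fit: a
single-well template (bright inner square framed by the darker wall band)
is replicated on a lattice parameterised by `(row_offset, col_offset,
row_pitch, col_pitch)`, and the parameters are chosen by a
differential-evolution optimiser (rand/1/bin, population 24, F = 0.7,
CR = 0.9, fixed seed) to minimise the mean absolute difference between the
min-max-normalised frame and the simulated grid. Grid dimensions come from
configuration, and rotation is not optimised because plates are
mechanically registered.

Because the normalised lattice image is an outer product of 0/1 row and
column bands, the objective reduces exactly to rectangle sums over a
summed-area table of `|I-1| - |I|`; a property test verifies equality with
the naive tiled-template objective. Well boxes are rounded to integer
pixel edges inside the objective, making it piecewise constant; the
optimum is insensitive to this at the sub-pixel level that matters
(fitted pitch within 1 px of truth on noiseless frames, mean IoU about
0.99 over 50 plates with pitch varied by 10% and up to 5% noise).

A fit whose residual exceeds `residual_ceiling` (default 0.3) — or a
degenerate constant image — is flagged `low_confidence` rather than
raised as an error, since a human can still review it. Wells can be marked
*bad* (`mark_bad_well()`); the flag propagates to tracks, feature rows and
aggregate exclusions downstream.

## Segmentation, tracking and motion modes

Putative worm objects are connected dark components (`threshold` default
100 grey levels, or Otsu over the well interiors) within
`[min_area, max_area]` (defaults 60–3000 px). Midlines come from
Zhang-Suen thinning of the component mask followed by the longest geodesic
path through the skeleton. The masked-video representation
(`mask_frame()`) zeroes every pixel further than `halo` (default 5 px)
from any object, which is also exactly how classifier ROIs are cropped.

Tracking is greedy nearest-neighbour linking between consecutive frames
(`max_step` default 12 px/frame, ample for 35 px/s at 25 fps); unmatched
detections start new tracks, a missed frame closes a track, and tracks
never merge — so the number of tracks typically exceeds the number of
worms, and identity is not maintained across gaps.

Motion modes are computed from the signed crawling speed: the centroid
velocity (central differences, which makes the quantity exactly
antisymmetric under time reversal) projected on the tail-to-head midline
axis and smoothed with a centred 0.4 s window. Speeds below `v_stat = 0.1`
body lengths/s are stationary; otherwise the sign decides
forward/backward. Head and tail are resolved per track by the majority
direction of motion (`resolve_head_tail()`, head leads while crawling
forward, ties left stable); keeping that step separate from
`classify_motion()` preserves the time-reversal antisymmetry of the
classification itself. The defaults recover 95%+ per-frame mode accuracy
on noiseless single-worm sessions; transitions are blurred by the
smoothing window, so accuracy is bounded by the transition rate.

## The worm/non-worm classifier

The filter is a small VGG-style convolutional network on 80x80 masked
grayscale crops: eight 3x3 stride-1 convolutions each followed by ReLU,
2x2 max-pooling after every second convolution (80 -> 40 -> 20 -> 10 -> 5),
batch normalisation on the third and seventh convolutions, dropout (0.5)
before a single fully connected 2-class output. With the default channel
plan (32, 64, 64, 128, 128, 256, 256, 256) the stack has 1,765,954
trainable parameters. The architecture outline alone does not pin the channel widths down, so
the plan is configurable and the parameter count is reported, not
asserted exactly. Training uses cross-entropy with Adam at learning
rate 1e-4, an 80/10/10 stratified split, early stopping on validation
accuracy (patience 5), and restores the best-validation weights; test
metrics come only from the untouched 10%.

Preprocessing shifts masked (exactly-0) background pixels to the 95th
percentile of the unmasked grey values — linear interpolation between
order statistics, stated because percentile conventions differ — and then
min-max normalises to [0, 1]; a constant image maps to all zeros.

The convolution and pooling kernels are implemented in C++
(im2col + GEMM); the backward pass is verified against finite differences
in the test suite. The `"small"` channel preset (8, 8, 16, 16, 32, 32, 32,
32) is used for synthetic-data work: the synthetic classes are separable
enough that it reaches 99%+ held-out accuracy on a 2000-image set in a few
minutes on one CPU, and the architecture (not the width) is what the
filtering protocol depends on. The worm class includes a share of
two-worm crops and both classes include crops overlapping the wall shadow
band, because that is what detection crops of multi-worm wells look like.

Track filtering applies the network to one ROI per second of track
duration (the first frame of each whole second — deterministic; tracks
shorter than a second use all frames) and takes the median worm
probability; a track is a worm if and only if the median is *strictly*
greater than 0.5. On simulated sessions with debris, evaluated by
attributing each detection to the truth objects inside its mask (tracks
dominated by neither class — worm-debris collisions — are ambiguous and
excluded from the rates), the filter keeps 95%+ of worm tracks and
removes 95%+ of pure debris tracks.

## Photoresponse statistics

The stimulus protocols are: **standard** — 5-min pre-stimulus video, 6-min
stimulus video with three 10-s pulses at 100% intensity starting at its
60/160/260 s marks, 5-min post-stimulus video (16 min total); **serial** —
5 min off, twenty cycles of 10 s on / 90 s off, 5 min off (2600 s).
Windows are half-open and aligned to frame-index timestamps, not frame
counts.

Per well and time point, mode fractions divide the worms in each mode by
the worms tracked at that time point; time points with no tracked worms
are undefined and excluded (never imputed as zero). Aggregation across
wells attaches 95% confidence bands from a nonparametric bootstrap (wells
resampled with replacement, n = 1000 by default; the calibration study in
the test suite uses 200 resamples over 200 replicates of 24 wells at 5 fps
and observes ~95% empirical coverage). Per-worm mode series can be
downsampled to 0.5 Hz by taking the prevalent mode in nonoverlapping 2-s
windows, with ties resolved conservatively as stationary > forward >
backward (no movement claimed on ties).

Per-pulse response deltas are the mean fraction in the 10-s window just
before the end of each pulse (the stimulated level) minus the 10-s window
just after it (the post-stimulus relaxation) — positive for a forward
escape response, summing to zero over modes, and growing over the pulse
series under simulated sensitisation (per-pulse light bias ramps). The
baseline shift is the difference between the final and initial 5 minutes
per mode, which picks up the fatigue-like drift towards the stationary
mode after serial stimulation.

## Feature pipeline

`summarize_features()` reduces each well's tracks to a single averaged
feature vector: body length and width, mean absolute curvature in five
equal-arc-length body segments (head, neck, midbody, hips, tail), overall
speed, per-mode time fractions, and per-mode signed speeds (catalogue in
`inst/extdata/feature_catalogue.csv`). Full behavioural-feature catalogues in this field run to thousands of
features; the machinery here is deliberately width-agnostic,
so the dimension contracts (3 periods x 3076 features = 9228; 3 x 256 =
768) hold by construction and are asserted on tables of exactly those
widths.

Feature tables travel as plain CSV with a sidecar missingness
convention — each feature column `f` is accompanied by a logical
`f__missing` column — so the mask survives serialisation
(`write_feature_table()` / `read_feature_table()`).

Quality control follows a fixed order: drop samples with more than 40% of
features missing; drop features missing in more than 20% of samples
within any interval group (the 10-s window in time-resolved mode, the
recording period in summary mode — one `interval` argument covers both);
impute remaining gaps with the within-interval feature mean; z-normalise
columns over the whole table. Uninputable and zero-variance features are
dropped with reasons in the QC report. The result is deterministic and
row-order invariant.

Downstream statistics delegate to the standard implementations behind
this package's interfaces: PCA via `prcomp` with a deterministic sign
convention (largest-magnitude loading positive); Kruskal-Wallis tests
(tie-corrected) with Benjamini-Yekutieli step-up control, chosen because
behavioural features are strongly dependent; hierarchical clustering of
z-scored fingerprints with complete linkage on 1 - Pearson correlation;
and a linear mixed model per (compound, feature) with imaging day as a
random intercept (lme4/lmerTest, Satterthwaite p-values), a compound
counting as a hit when any feature survives Benjamini-Hochberg across
features at q. BH is the package's choice of within-compound
multiplicity step and is an argument, not a constant. Compounds observed on a single
day are unestimable and excluded; where the random-effect fit fails the
model falls back to a fixed day effect. Constant features give p = 1, not
an error. For two untied groups an exact Kruskal-Wallis p is available
through the exact Wilcoxon rank-sum distribution, which matches a complete
enumeration of the permutation tail; the asymptotic chi-square
approximation is off by an order of magnitude that far in the tail, which
is why both are offered.

## Strain classification protocol

The protocol runs the classification analysis end to end and guards its
key property — no information flow from the test set into any selection
or tuning step — with an audit log (`audit_no_test_leak()`):

1. stratified hold-out of a rounded 20% of each strain;
2. for each candidate feature-set size in {2^7..2^11} (clipped to the
   table width): within each CV training fold, recursive feature
   elimination with random-forest impurity importances down to the size,
   a fit, and a score on the fold's held-out part; repeated with fresh
   fold assignments; the best mean-accuracy size wins and its feature set
   is re-selected on the full training set;
3. grid-search CV over the random-forest hyperparameter grid
   (n_estimators 200..2000 by 200; max_features auto/sqrt — "auto"
   meaning all features, the historical convention; max_depth 10..110 by
   10 plus unlimited; min_samples_split 2/5/10; min_samples_leaf 1/2/4),
   refit on the whole training set, and one evaluation on the untouched
   test set against chance = 1/(number of strains) — 9% for an 11-strain
   panel.

Open choices, documented and configurable: the RFE step drops 10% of the
remaining features per iteration (`"full"` preset) and the CV uses 4
folds with 20 repeats; the `"fast"` preset (3 folds, 3 repeats, 50% RFE
steps, a reduced grid, 100-tree forests) exists because the full
2160-point grid is feasible but slow, and is what the routine test runs
use. Forests are ranger with single-thread determinism;
min_samples_split/min_samples_leaf map to `min.node.size`/`min.bucket`.

## Metadata provenance

The experiment records are plain CSV files; the file names follow the
field's convention and the column schemas are defined by this package:
`wormsorter.csv` (plate, well range, strain, media, bacteria — ranges are
inclusive rectangles like `A1-B12` or comma lists, matching how sorters
dispense row blocks), `manual_metadata.csv` (date, run, plate, instrument,
environment), `sourceplate.csv` (compound contents of source-plate wells),
and the source-to-imaging well mapping: `robotlog.csv` when the liquid
handler shuffled columns, `imaging2source.csv` (identity) when it did not.
Compilation expands ranges, joins compounds through the well mapping, then
joins the run log and the recording index into one row per (video, well of
that camera's 4x4 block), with camera 1..6 tiling the plate 2 x 3 so
camera 1 sees A1..D4 and camera 6 sees E9..H12. All joins are inner with
hard errors on unmatched keys — fail-fast provenance rather than silent
drops — and `validate_metadata()` reports uniqueness/completeness
violations machine-readably. The fixture generator constructs the expected
final table independently of the compilation code, and the round trip is
asserted byte-for-byte, including through CSV files on disk.

## Problem sizes used in validation

The routine test suite and acceptance checks run at scales chosen to
exercise every code path while staying desk-sized: 50 synthetic plates for
the detection study; a 2000-image ROI set (1000/class, `"small"` channel
preset, 8 epochs) for the classifier; a 12-s 2x2-well session with 12
worms and 16 debris objects for filtering; 24-well chain simulations
(reduced frame rates, which leave stationary behaviour unchanged) for the
photoresponse calibrations with 200 coverage replicates at 200 bootstrap
resamples; 11 strains x 20 wells x 768 features for the classification
protocol with the fast preset. Paper-scale runs (full 16-min sessions at
25 fps, the 2160-point grid, 1000 bootstrap resamples) use the same code
with the default parameters.

## Known limitations

* The tracker has no pose model: midlines come from skeletonisation, so
  self-overlapping postures (omega turns) produce unreliable midlines, and
  merged worms are a single putative object until they separate.
* Motion-mode accuracy is limited by the smoothing window around
  transitions; dense switching (several per second) will blur.
* The CNN presets are tuned for synthetic contrast statistics; real video
  would need retraining on annotated crops, and the reported synthetic
  accuracies do not transfer.
* The LMM screen fits one model per (compound, feature) and is not
  optimised for the full drug-library scale; at thousands of features it
  is the slowest stage.
* `aggregate_bootstrap()` resamples wells only; it does not model
  within-well worm correlation beyond what the well means carry.
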