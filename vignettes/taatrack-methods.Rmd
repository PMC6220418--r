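---
title: "Measuring flower-opening time from panicle time-lapse imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring flower-opening time from panicle time-lapse imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taatrack)
```

## The measurement problem

Grass florets open for minutes to hours, often at night, and the clock
time at which the anthers first protrude — the time of day of anther
appearance, TAA — is a heritable phenotype of agronomic interest
(early-morning flowering escapes midday heat sterility in rice, for
example). Scoring TAA by eye requires a person watching panicles around
the clock; scoring it from time-lapse imagery requires solving two quite
different vision problems:

* **Daytime frames** are RGB and texture-rich. Open and closed spikelets
  are visually distinct (exposed anthers are bright), so a supervised
  tile classifier works well.
* **Nighttime frames** are captured under infrared illumination and lack
  the colour features the day classifier depends on. What *is*
  distinctive about an opening event at night is movement: anther
  protrusion changes local pixel intensity abruptly relative to the slow
  drift of the growing panicle.

`taatrack` implements both detectors, the rate statistics built on top
of them, companion morphometrics (bristle density, leaf growth, leaf
emergence timing), and seeded synthetic generators that produce
ground-truthed inputs for every stage.

## Daytime pipeline

### Tiling geometry

Frames are cut into 34 x 34 pixel tiles (the classifier's input size).
A frame whose dimensions are not multiples of 34 is first resized with
bilinear interpolation, truncating each dimension *down* to the nearest
multiple: a 1000 x 500 frame becomes 986 x 476. Truncation (rather than
rounding to the nearest multiple) is fixed by the package's worked
example and keeps the operation idempotent. Tiling is an exact
partition: reassembling the tiles reproduces the resized frame
bit-exactly, which the test suite asserts.

Annotations use the LabelImg/VOC XML dialect with 1-based inclusive
boxes; they are converted at the parse boundary to 0-based, half-open
row/column boxes, the only convention used internally.

### The classifier contract

The classifier is a *contract*, not an architecture: any backend that
maps a 34 x 34 x 3 crop to a `(background, closed, open)` probability
triple summing to one can stand behind `classify_image()`. The package
bundles two desk-scale reference backends:

* `"multinom"` (default): multinomial logistic regression on bilinearly
  downsampled pixel features (17 x 17 x 3 by default, a clean 2x
  reduction of the crop);
* `"nnet"`: a single-hidden-layer network on the same features.

Large convolutional architectures are deliberately out of scope — the
pipeline, not the network, is the contribution, and the bundled
backends separate the synthetic classes essentially perfectly while
training in seconds on one CPU. The training configuration exposes
`rounds` (optimiser iteration cap, canonically 250) and an L2 `decay`;
`learning_rate` and `momentum` are carried in the config for SGD-style
backends but do not apply to the BFGS optimiser the bundled backends
use.

Training corpora follow the canonical 10:2:1 background:closed:open
proportion (5,000/1,000/500 at full scale; the tests use 1,000/200/100)
with a disjoint, seeded validation split (500/50/50). Open-vs-closed
accuracy is computed only over crops whose true label is open or
closed, and a background prediction on such a crop counts as an error —
the stricter of the possible readings.

### Open ratio

`open_ratio()` is `n_open / (n_open + n_closed)` over tile calls;
background tiles are excluded. Tiles straddling a spikelet boundary are
counted as called, with no ownership resolution — the ratio is a
whole-image summary, not a census.

## Nighttime pipeline

Spikelets that the classifier calls *closed* on the last light frame are
tracked through the night by cropping their (padded) bounding box out of
every IR frame. Each per-spikelet stack is processed independently:

1. **Drift stabilisation.** Each frame is translated by the
   integer-rounded shift aligning its intensity centroid with the first
   frame's centroid. Integer shifts keep the operation deterministic and
   avoid interpolation artefacts; anchoring to the first frame (rather
   than chaining frame-to-frame) avoids accumulating rounding error. A
   validity mask records the pixels observed in every shifted frame, and
   all change fractions are computed over that mask only.
2. **Windowed differencing.** The stack is segmented into consecutive
   30-minute windows. Within a window, every frame is differenced
   against the window's first frame; a pixel "changes" when its absolute
   difference exceeds 50% of the bit-depth maximum (127.5 for 8-bit),
   and a frame triggers when at least 5% of valid pixels change. The
   comparison is `>= 5%` and `> 50%`, following the rule's wording.
3. **Earliest event wins.** Opening movement often spans several
   minutes and can trigger several windows; the earliest triggering
   frame's own timestamp is the TAA.

Two deliberate interpretations are worth recording. "Max pixel
intensity" is read as the *bit-depth* maximum, not the per-window
observed maximum, so the criterion is stable in all-dark windows (both
are config-overridable via `motion_config()`). And each window's
reference frame is additionally differenced against the first frame of
the *following* window: a window's first frame is its own reference, so
without this one-frame overlap an event landing exactly on a window
boundary would be invisible to both adjacent windows — a blind spot we
observed directly on simulated data before adding the overlap.

The detector's equivalence with a naive per-pixel brute-force
implementation is asserted on random stacks, and its output is invariant
to a global integer translation of all frames.

## Flowering curves, rates and accession comparison

Night opening calls carry no absolute open-fraction scale (the
classifier cannot run on IR frames), so the cumulative count of night
openings is mapped affinely onto the open ratios measured on the last
light frame before dusk and the first light frame after dawn. The
anchored curve is non-decreasing and hits the anchors exactly; a night
with no openings maps to the constant dusk ratio.

The flowering *rate* is the first derivative of a cubic smoothing
spline fitted to the anchored curve. No smoothness parameter is imposed
by default — generalized cross-validation chooses it — but `df` and
`spar` are exposed because GCV on very smooth synthetic curves can
under-smooth. Rates are normalised by each panicle's maximum rate, so
accessions with different spikelet counts are comparable; when no
flowering occurred the normalised rate is defined as all-zero rather
than dividing by a numerically-zero peak.

Accessions are compared by summarising each replicate panicle with its
mean normalised rate inside a clock window (canonically the 1.5 h after
dusk, 20:00-21:30, where accession differences are strongest), then a
classical one-way ANOVA across accessions (one panicle = one replicate,
df = (k-1, N-k)) and Holm-adjusted pairwise t-tests with a pooled
standard deviation (the classical pairwise procedure; Welch is
switchable). Two conventions: all-identical constant groups report
F = 0, p = 1 with a warning instead of 0/0; and the window *mean* is the
replicate summary, since on a uniform one-minute grid it matches a
trapezoidal integral to well under the test tolerances.

## Morphometrics

**Bristle density** is the bristle count divided by panicle height,
averaged over a series of binary masks. The counting rule — a bristle
counts when its base connects to its tip through continuous white
pixels — needs concrete base/tip operators, which we define
morphologically: the panicle *body* is the mask opened with a disc
larger than any bristle width; every 8-connected component of the
remaining white pixels is a candidate; a candidate counts when it is a
thin branch (inscribed half-width at most 2 px) attached to the body
(the base is the body pixel at the attachment) whose farthest pixel
from the body (the tip) lies at least `body_brush/2 + 2` px out. The
thinness criterion rejects the wide, shallow slivers a morphological
opening shaves off convex body corners. This is one concrete reading of
an operator the original description leaves unspecified; it reproduces
the stated counting rule and is exact on the synthetic panicles
(0-20 bristles) in the test suite. The 8-connected component labelling
is implemented in the package (two-pass union-find) because the
available image libraries label 4-connected components only, which
would split diagonal bristle runs.

**Panicle height** fits a least-squares line through each flank's
bristle bases (flanks split by the body centroid column); the apex is
the intersection row when the lines intersect above the lowest base,
otherwise the first white non-bristle row from the top. Height is the
image bottom row minus the apex row, matching the full-height-rectangle
convention (height = image height - 1).

**Leaf midline length** takes, for every mask row, the midpoint of the
leftmost and rightmost white pixels and sums Euclidean distances
between successive midpoints, bridging empty-row gaps with the straight
segment between the surrounding midpoints. Raw midpoints are used — no
subpixel smoothing — so a 100-row vertical strip measures exactly 99 px
and a 45 degree band 99 * sqrt(2) within interpolation tolerance.
Day/night growth partitions alternate dawn/dusk lengths; small negative
increments are clipped to zero as measurement noise, with a warning.

**Leaf emergence timing** bins event hours into 24 fractions summing to
one and fits a cubic smoothing spline with 3 equivalent degrees of
freedom to the bin values. The spline is fitted on the linear 0-23 hour
axis without circular wrap-around; profiles peaked very near midnight
would be smoothed less faithfully there, a known limitation.

## Capture-parameter optimisation

Night image quality depends strongly on capture settings, so the
package ships an exhaustive search over a finite option grid, scoring
each captured frame by the number of pixels whose 3 x 3 Sobel gradient
magnitude exceeds a threshold (default half the bit-depth maximum —
the operator and threshold are package choices, config-exposed, since
only "edge count" is specified). The capture function is injected by
the caller (hardware driver or simulator); every combination is
evaluated exactly once, failures are skipped with a warning, and ties
break by lexicographic enumeration order.

## What the synthetic generators do and do not emulate

The generators render deliberately simple scenes: textured backgrounds,
green ellipses for closed spikelets, ellipses with bright protruding
dots for open ones, dim blobs plus a bright anther patch for night
crops, triangular bodies with one-pixel strokes for panicle masks,
constant-width strips for leaves. They *do* emulate the structural
features the operators depend on — class-distinctive colour and
brightness, localized intensity change at scripted times, global
integer drift, Gaussian sensor noise, base-tip bristle geometry,
known-length midlines, wrapped unimodal emergence times — and every
generator is a pure function of its seeded spec, bit-identical across
runs.

They do *not* emulate occlusion, defocus, specular highlights,
illumination gradients, overlapping spikelets, panicle growth between
frames, or the gradual multi-minute opening motion of real florets
(synthetic openings are step changes). Passing the synthetic benchmarks
therefore demonstrates that the operators implement their contracts
exactly, not that any particular accuracy carries over to field
imagery. In one respect the night generator is deliberately realistic:
spikelet-blob contrast against the background (about 95 intensity
units) is kept *below* the 50% change criterion, as in IR imagery where
only emerging anthers are bright, so residual one-pixel stabilisation
error cannot masquerade as an opening.

Default generator conditions mirror the study design: 12 h : 12 h
photoperiod with dawn at 8:00 and dusk at 20:00 (the boundary instant
belongs to the period it starts), one frame per minute, 720-frame
nights, 8-bit intensities, noise sd 8, drift up to +/-3 px, opening
amplitude 0.8 of bit depth over at least 10% of the crop. The
full-scene simulator places spikelets on the 34-px tile lattice so that
tile calls correspond one-to-one with spikelets — a simplification that
isolates the night detector's behaviour from tile-ownership ambiguity.

## Problem sizes and numerical choices in the tests

The test suite runs entirely on synthetic data at desk scale, chosen to
exercise every contract in a few minutes on one CPU: classifier corpora
of 1,300 training + 600 validation crops from 25 seeded scenes;
30-series night benchmarks with 720-frame stacks; 100 random
16 x 16 x 60 stacks for brute-force equivalence; 1,000 null
simulations for the ANOVA type-I check; panicles with up to 20
bristles; one full simulated experiment (9 spikelets, 720-minute night)
for the end-to-end and reproducibility checks. Tolerances follow the
contracts: bit-exact where exactness is promised (tiling, reassembly,
reruns under a fixed seed), 1e-10 against the ANOVA oracle, 1% relative
for spline slope recovery, and exact integer equality for bristle
counts.

## Known limitations

* The day classifier backends are linear-in-features models; real
  imagery with subtle open/closed differences will need a stronger
  backend behind the same contract.
* Stabilisation assumes the spikelet dominates its crop's intensity
  centroid; a bright neighbour drifting through the crop would bias the
  shift estimate.
* Re-closing is not modelled: a spikelet opens at most once.
* The emergence spline does not wrap at midnight.
* Interactive region selection (manual panicle or leaf cropping) is
  replaced by explicit bounding boxes or pre-made masks.
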