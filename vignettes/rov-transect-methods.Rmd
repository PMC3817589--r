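---
title: "Methods: ROV transect quantification and depth-break inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROV transect quantification and depth-break inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rovcoral` re-implements, as a tested pipeline, the quantification and
statistical analysis of vertical ROV video transects used to map a
cold-water coral's distribution against depth and physico-chemical
gradients in a stratified fjord. This vignette is the package's own
account of the underlying models, the choices that were genuinely open,
and what the test suite does and does not demonstrate.

## Survey model

A survey consists of a small number of dive sites along the fjord axis.
At each site the ROV flies one downward and one upward vertical transect;
video frames are extracted on a regular cadence, each frame carrying an
echo-sounder range (camera to substrate) and a CTD depth. Manual
annotation of each frame yields the analysed area, the non-sediment rock
area suitable for settlement (*available substrate*), the coral-covered
area (*patch size*), a coral count, and length/width measurements for
adequately oriented individuals.

### Frame geometry

Frames are scaled with a pinhole model under the assumption that the
camera axis is held perpendicular to a locally planar substrate (the
vehicle's pitch is adjusted during the dive to keep it so):

$$w = 2\,d\,\tan(\theta_h/2), \qquad h = 2\,d\,\tan(\theta_v/2),$$

with $d$ the echo-sounder range (m) and $\theta_h, \theta_v$ the
horizontal and vertical angles of view. No obliquity or lens-distortion
correction is applied. The angles of view of a given camera are required
configuration, not constants: `camera_model()` defaults to 60° × 40° at
1920 × 1080 px, a plausible HD underwater camera, and every geometric
quantity follows from whatever is supplied.

### Placement, worldfiles, overlap exclusion

The analytic coordinate system puts CTD depth on the y axis (positive
down) and assigns x arbitrarily but reproducibly: one vertical lane per
(site, transect), ordered by the along-fjord site sequence with the down
transect before the up transect. Lane pitch is 1.5 × the widest frame, so
lanes can never intersect; the factor is arbitrary above 1 and only needs
to keep neighbouring transects "next to each other but not overlapping".

Worldfiles use the standard six-line ESRI affine form (A, D, B, E, C, F).
Map space is y-up, so depth enters negated and E is negative, while the
pipeline's analytic depth stays positive-down. Numbers are written in
fixed decimal notation with 12 significant digits — comfortably beyond
the 9 the format needs and few enough that write → parse → write is
bit-stable (verified over 1000 random frames).

The original workflow excluded overlapping frames without stating a rule.
We chose a **greedy, order-respecting rule**: frames are processed in
acquisition order within their lane and retained iff the intersection of
their rectangle with the union of previously retained rectangles is at
most a tolerance (default exactly 0; touching edges are allowed since a
zero-area intersection excludes nothing). The rule is deterministic,
reproducible, and reduces — for same-lane frames, which always overlap in
x — to 1-D interval logic, which is what the test suite's independent
brute-force oracle exploits. Whether the original study dropped partially
overlapping frames or only fully redundant ones is unknowable from the
text; the tolerance knob covers both readings.

### Coral quantities

A *patch* is the coral aggregation within a single frame (one annotation
row, never subdivided — multiple clusters inside one frame are one patch
at the defined granularity). A *bank* is a maximal run of at least three
consecutive retained frames each bearing a patch; adjacency is positional
within a lane after exclusion, and a single coral-free frame interrupts a
run (no bridging — the definition says "extending over" the frames).
*Shape* is length over mid-length width for measured corals only;
individuals counted but not measurable (oblique, partly hidden) carry no
shape and affect counts alone.

## Depth binning

All per-frame quantities are aggregated per site into half-open
`[10k, 10(k+1))` m intervals: surfaces are summed, coral patch size,
abundance, shape and the CTD parameters averaged, and
`% used = 100 × patch size / available substrate` computed from the bin
totals (which keeps it in [0, 100] by construction). A depth exactly on a
boundary belongs to the deeper interval; bins with no frames are omitted;
every bin is labelled by its centre, so the deepest data point plots at
its interval centre even if the dive ended mid-interval.

Two conventions were genuinely open:

* **Abundance denominator.** The per-bin abundance is the mean coral
  count per retained frame (frames without corals contribute zeros),
  which is area-stable and preserves the zero-inflation of sparse depths;
  a flag (`abundance = "per_patch_frame"`) restricts the mean to
  patch-bearing frames for the within-patch reading.
* **CTD join.** The cast and the frame stream are recorded by different
  sensors; records are attached to frames by nearest depth within the
  same site before averaging. At the generator's 1 record/m resolution
  the nearest-depth error is at most 0.5 m.

CTD summaries use the sample (n − 1) standard deviation, the convention
behind "mean ± SD" site-statistics tables, and treat the sensor pH as-is
(NBS-buffer calibration; no scale conversion is attempted). Parameters
with no valid values at a site — e.g. a withheld salinity channel — are
reported absent, never as zeros. Section grids are bin-averages on the
same 10-m intervals; summaries default to pooling down- and up-cast
records, with a `cast` filter because sections are conventionally drawn
from down-casts only.

## Inference layer

**Break split.** The abundance break is described by a divider band of
depth lines (270–280 m); the default break depth 275 m is the band
centre. A bin whose interval contains the break goes to the *above*
group (operationally: above iff `bin_lower_m < break`). Either group
being empty is an error, not a silent answer.

**Rank-sum test.** `wilcoxon_two_sample()` uses midranks; for combined
sizes ≤ 12 without ties the two-sided p-value comes from exhaustive
enumeration of all $\binom{N}{n_a}$ rank assignments, otherwise from a
normal approximation with tie correction and continuity correction. The
suite checks enumeration against an independent pairwise-count oracle
(max |Δp| < 1e−12 for all group sizes ≤ 6) and against `stats::wilcox.test`.

**Permutation test.** The original analysis added a 10,000-repetition
permutation test because only two stations reached below the break. The
permuted unit, the statistic and the sidedness are not stated; we permute
*bin values*, use the difference of group means, and test one-sided
(above > below) because the hypothesis is directional — all three are
configurable. The estimator is the add-one Monte-Carlo correction
$p = (1 + \#\{T^\ast \ge T\})/(B+1)$, which cannot return zero and counts
ties as extreme; ties must count for two identical constant groups to
give p = 1 and for the type-I error not to exceed the nominal level.
"Confirmed with 95% probability" is read as significance at α = 0.05.

**Regressions.** The tabulated analysis is headed "multiple linear
regression" but lists one predictor per row with occasionally negative
r², implying per-predictor fits reported as adjusted r². The default is
therefore simple OLS per predictor, reporting
$\bar r^2 = 1 - (1-r^2)(n-1)/(n-p-1)$, with `joint = TRUE` for the true
multiple fit. Missing predictor values drop rows pairwise, so one dead
salinity channel costs only the salinity rows. Surface-layer exclusion is
depth-based (bin centre above the halocline depth, default 10 m) rather
than salinity-based, since the layer is defined by the halocline at
roughly 7–10 m; the threshold is a parameter.

## The synthetic generator

The generator is the package's substitute for field data: it emulates the
survey's *structure* (7 sites with the canonical maximum dive depths, two
vertical transects each, frames on a regular grid, co-registered CTD, a
four-layer water column, an abundance break at 275 m) with known ground
truth, so recovery can be tested.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `break_depth_m` | 275 m | centre of the 270–280 m divider band |
| `abundance_drop_factor` | 5 | a strong, clearly detectable contrast |
| `halocline_depth_m` | 7 m | observed extent of the brackish layer |
| `frames_per_metre` | 2 | the 10-s frame cadence mapped to depth via an assumed constant descent; no descent speed is published, so this is a free parameter |
| `echo_distance_mean_m`, `_sd_m` | 1 ± 0.2 m | a close-range benthic survey; also unpublished, chosen once |
| `coral_density_m2` | 100 /m² | dense but below reported wall maxima |
| `substrate_fraction_mean`, `_conc` | 0.5, 1.5 | patchy rock/sediment cover with high variance (U-shaped beta) |
| `occupancy_mean` | 0.3 | corals on much, not all, available rock |
| `count_dispersion` | 1.5 | overdispersed (negative binomial) counts; aggregation is patchy and no count distribution is published |

Coral counts per frame are negative-binomial with mean
`density(depth) × available substrate`, where the density is 0 above the
halocline, the configured value between halocline and break, and that
value divided by the drop factor below — so the expected *per-area*
abundance below the break is exactly the above value over the drop
factor. Frames with zero counts carry zero cover.

Two structural choices deserve emphasis:

* **Substrate is geology, not effort.** The rock fraction is drawn once
  per site and 10-m depth stratum (outcrop-scale patchiness shared by
  both transects), and a frame's available substrate is that fraction
  times the *nominal* frame area, capped by the frame's actual footprint.
  Availability therefore does not track the analysed area — the
  representativeness property the original survey verified (r² < 0.05
  for available substrate vs. surface analysed). Modelling availability
  as fraction × actual footprint would hard-wire the opposite.
* **Deterministic expectations.** The ground truth records the expected
  per-bin abundance computed from the depth grid and a quadrature over
  the echo-range and substrate-fraction distributions, not from
  simulation; a 200-seed Monte-Carlo test checks generated bins against
  it within three standard errors.

What the generator does **not** emulate: imagery pixels, tides and
currents, larval dispersal, spatial autocorrelation of coral cover along
a wall, sediment smothering dynamics, or inter-annual change. Passing
tests therefore demonstrate the correctness of the quantification and
inference machinery under the stated stochastic model — not that the
model captures every feature of real fjord data.

## Numerical choices and degenerate inputs

* Echo ranges are truncated-normal (> 0) by rejection; the truncation is
  ignored in expectations (negligible at mean/sd ≥ 5).
* Geometry errors are raised, not patched: non-positive ranges, angles of
  view outside (0°, 180°), zero pixel counts, negative depths.
* Overlap tolerance comparisons use a 1e−12 absolute guard so that exact
  edge-touching is never excluded by floating-point noise.
* Permutation extreme-counting uses a relative 1e−12 guard so that
  relabellings that tie the observed statistic count as extreme.
* `percent_used()` distinguishes 0/positive (0%), 0/0 (undefined,
  missing) and positive/0 (data inconsistency, error).
* Annotation invariants (coral ≤ available ≤ analysed, cover implies
  count ≥ 1) are validated with a 1e−9 area guard before quantification.

## Problem sizes used by the tests and acceptance script

The suite runs on synthetic surveys sized for a desk machine: the
geometry oracle on a 10 × 10 (range, angle) grid; 1000 random worldfiles;
500 random transects against the brute-force interval oracle; rank-sum
enumeration for all group sizes up to 6; type-I error over 1000 null
datasets of 12 + 12 values at 500 permutations; break recovery over 200
seeded three-site surveys to 365 m with B = 10,000; and the
representativeness regression pooled over five full seven-site surveys
(915 bins). The full default pipeline (7 sites, ~7000 frames, 183 bins,
B = 10,000) runs in seconds.

## Known limitations

* The pipeline starts at frame metadata: video decoding, frame
  extraction and polygon digitisation are out of scope, as are true
  geographic projection, mosaicking and bathymetry.
* Bank detection is 1-D within a lane; aggregations continuing across
  the down/up lane boundary of the same wall are counted twice.
* The nearest-depth CTD join ignores the time offset between cast and
  frame acquisition.
* Regressions are ordinary least squares over bins treated as
  independent; depth bins of one transect are in reality serially
  correlated, so reported p-values are optimistic. (The original
  analysis shares this property; no multiple-testing correction is
  applied across the regression grid.)
* The carbonate system (aragonite saturation) is deliberately not
  computed; the CTD layer stops at the measured channels.
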