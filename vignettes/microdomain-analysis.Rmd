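---
title: "Activity-based detection and analysis of calcium microdomains"
author: "CaMicroDomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based detection and analysis of calcium microdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaMicroDomains)
```

# Scope

Astrocytes respond to nearby synaptic activity with spatially confined
Ca^2+^ transients — *microdomains* — in their somata, vascular endfeet
and fine processes. `CaMicroDomains` implements an activity-based
pipeline for detecting such microdomains in two-photon fluorescence
movies (membrane-tethered Lck-GCaMP6f for astrocytes, cytosolic
RCaMP1.07 for neurons), for quantifying the resulting events (dF/F
amplitude, AUC, onset latency after whisker stimulation, adaptation
slope), for population-level summaries (fast/delayed onset classes,
neuronal responsiveness tiers, pairwise synchrony, repeated-response
scores, barrel-area-normalized ROI counts), and for scoring the
whisker-dependent texture-discrimination behavior that such circuits
support. A synthetic-data module generates ground-truthed movies and
trajectories with the statistical structure the analysis assumes, so
every stage is verifiable end to end without access to raw recordings.

# The detection model

## Active pixels

Each pixel's trace is compared against a sliding temporal boxcar of 5 s
(config `boxcar_s`), centered on the current frame and truncated — not
padded — at the movie edges; truncation avoids phantom onsets at the
start of a trial. A pixel-frame is *active* when two criteria hold:

1. **Amplitude.** The intensity strictly exceeds the boxcar mean plus
   `amp_sd_mult` times the pixel's noise SD (7 for in vivo movies of
   either channel, 5 for in vitro Lck-GCaMP6f).
2. **Timing.** The local event containing the frame has a peak rise
   time within `rise_bounds_s` (0.07–1 s in vivo RCaMP1.07, 0.1–1 s in
   vivo Lck-GCaMP6f, 0.1–8 s in vitro). We operationalize the rise time
   as the interval from the last upward crossing of the boxcar mean to
   the local peak of the contiguous above-mean run — the simplest
   definition consistent with the stated bounds. This is an
   interpretation: the timing criterion is stated only as "peak rise
   time relative to the boxcar".

**The noise scale is estimated robustly, not as the within-window SD.**
This is a deliberate numerical choice. A Ca^2+^ transient lasting a
second or two occupies a substantial fraction of its own 5-s boxcar, so
it inflates the classical window SD roughly in proportion to its own
amplitude; the ratio of peak height to window SD then saturates near
3–4 *for any event amplitude* (we verified this on linear-rise /
exponential-decay kernels across decay constants of 0.3–1.5 s), and a
7×SD criterion could never fire. `pixelNoiseSd()` therefore estimates
each pixel's noise as

$$\hat\sigma = \frac{\mathrm{median}\,|x_{t+1} - x_t|}{\sqrt{2}\,\Phi^{-1}(3/4)},$$

the standard robust estimator for fluorescence traces: for iid Gaussian
noise it is consistent for the SD, and a transient occupying a minority
of frames barely moves the median of the first differences. A constant
trace has $\hat\sigma = 0$ and — because the amplitude criterion uses a
strict inequality — can never exceed its own threshold, which resolves
the 0 > 0 ambiguity for zero-variance pixels. `boxcarStats()` still
returns the classical windowed mean and unbiased SD, each checked
against brute-force oracles in the test suite.

Whether the boxcar is centered or trailing is configurable
(`boxcar_align`); centered is the default.

## From active pixels to ROIs

Active pixel-frames are grouped within space (Euclidean radius 4 µm)
and time (0.2 s for RCaMP1.07, 0.5 s for Lck-GCaMP6f) by transitive
closure (single linkage). The implementation first takes within-frame
connected blobs and single-links blobs by minimum pairwise distance —
provably identical to the exact pairwise closure whenever the radius is
at least $\sqrt 2$ px (neighbor chains are shorter than the radius),
with a direct pairwise fallback below that; the exact pairwise
union-find oracle is retained in the tests.

Each spatiotemporal component is projected along time by counting
active frames per pixel, normalized and thresholded at $q = 0.2$, and
reduced to its largest 4-connected region to give a 2D ROI footprint.
The normalization denominator is the component's own maximum count by
default (`normalization = "component"`); a global-maximum option
exists because the choice of denominator is genuinely open. Footprints
of temporally distinct components may overlap; each keeps its own ROI
identity, and "each ROI is unique" is enforced only against manually
drawn compartment masks (below).

## False-positive control

Raw intensities inside each 2D ROI are compared with a surround ring by
one-way ANOVA; the ROI is kept iff $p < 0.05$. Two details the
criterion leaves open were fixed as follows:

* **Sample unit.** The per-pixel *temporal mean* over the ROI's active
  frames, not pixel-frames — pixels are the independent unit, and using
  pixel-frames would pseudo-replicate in time and inflate rejection.
  With this choice, ROIs drawn on pure noise are retained at the
  nominal 5% rate (type-I calibration is an acceptance test).
* **Surround geometry.** A 2 µm-wide dilation of the footprint,
  excluding all ROI pixels (width configurable; no width is stated for
  the original ring). An ROI whose surround is entirely consumed by
  neighboring ROIs is retained with an `untestable` flag and a warning;
  a zero-variance degenerate comparison gets $p = 1$ and is removed.

Automatic ROI pixels overlapping any manually drawn compartment ROI
(somata, endfeet, neuronal somata identified with SR101 or by
fluorescence) are removed, and surviving automatic ROIs classify as
*processes*.

# Event metrics

Per ROI, dF/F is the footprint-mean raw trace normalized to its mean
over the first 5 s of the trial. Events are local maxima with height
above 2.5 baseline SD and prominence at least 2 baseline SD (the
prominence floor is our choice — the original event finder is a generic
peak routine with unstated settings — and ties the operating point to
the trace's own noise; it is exposed as `peak_min_prominence_sd`).
Onset latency is the first time after stimulus onset at which the
5-frame moving-average-smoothed trace strictly exceeds 2.5 baseline SD,
reported at frame resolution without sub-frame interpolation. AUC is
the trapezoidal integral over the 8-s analysis window by default; a
per-event-span mode exists because the integration span is genuinely
open. The adaptation slope is the OLS slope of dF/F against time over
0.5–1 s after stimulus start.

Trial timing is explicit (`TrialProtocol`) because the acquisition
description and the analysis windows do not pin a single consistent
arithmetic; defaults are 5 s baseline, stimulus at 5 s, an 8-s analysis
window, 25-s trials at 13.84 fps (in vitro preset: 256×256 px at
2.58 fps).

# Population metrics

* **Fast/delayed.** A microdomain with onset latency strictly below the
  median neuronal onset latency is *fast*; ties are *delayed* (the
  fast class requires "less than"). The reference median is computed
  from the cohort's responding neurons, or supplied directly (reported
  cohort values: 1.71 s control, 1.78 s knockdown).
* **Tiers.** Neuronal event amplitudes partition into low (< 1.92
  dF/F), mid ([1.92, 3.47)) and high (≥ 3.47) tiers; the cutoffs are
  the 88th/98th percentiles of the control amplitude distribution,
  which is well described as log-normal. `calibrateAmplitudeModel()`
  inverts the two-quantile system to recover the log-normal parameters,
  and the synthetic module samples neuronal amplitudes from it.
  Where the narrative says "> 98th percentile" but the operational
  definition writes "≥ 3.47", the inequalities of the operational
  definition are used.
* **Synchrony.** Pearson correlation between the dF/F vectors of every
  ROI pair in a field of view over the 0–8 s stimulation window, with
  t-distribution p-values; pairs enter the synchrony summary iff
  p < 0.05. No multiple-testing correction is applied by default — a
  faithful-reproduction choice, since only "significant p-value" is
  stated — with Benjamini–Hochberg behind `corr_adjust = "BH"`. The
  summary averages within trial and then across trials; a pooled mode
  exists because the pooling order is not fully specified.
* **Normalization.** ROI counts are scaled to the 32,000 µm² reference
  whisker-barrel area so fields of view of different sizes compare.
* **Astrocyte area.** The "total astrocyte area" used by the
  active-pixel fraction and the repeated-response score is not defined
  operationally anywhere; the default is Otsu's threshold on the
  temporal mean image, overridable by a supplied mask.

# The synthetic-data generator

`generateMovie()` renders `baseline × (1 + Σ events) + noise`: each
planted event has a contiguous footprint, a linear rise to its
amplitude over `rise_s`, and an exponential decay with constant
`decay_s`, applied multiplicatively to the baseline within the
footprint. The kinetic shape is the simplest one with a well-defined
rise time matching the detection gate. Noise is additive Gaussian by
default — the detection criteria are SD-based, so Gaussian suffices to
verify the thresholds — with Poisson shot noise as an option. The
baseline is a smoothed Gaussian random field rescaled to mean 100 and
spatial SD 10, mimicking diffuse astropil texture; a uniform baseline
is available for closed-form oracle tests. Generators are pure
functions of (spec, seed).

Default study conditions (`randomSyntheticTruth()`): 128×128 px at
13.84 fps and 1 µm/px, 25-s trials with 5-s baseline, 10 disc-shaped
events of radius 2–4 px with amplitudes 1–4 dF/F, rise 0.3–0.5 s,
decay 0.6–1.0 s, half stimulation-locked and half spontaneous, and
centroid separation at least 15 µm so the 4-µm grouping radius cannot
merge distinct planted events. No SNR is reported for the original
movies; the default noise SD of 5 (5% of the baseline mean) gives peak
SNRs of roughly 20–80 for amplitudes 1–4 dF/F — comfortably above the
7× gate, as expected for bright indicator transients — and is a config
knob, not a claim about real data.

What the generator deliberately does **not** emulate: optical PSF
blur, motion artifacts, bleaching, biophysical indicator kinetics,
overlapping events on one pixel, or spatially varying amplitude within
a footprint. Passing recovery tests therefore demonstrates the
correctness of the detection logic at realistic SNR, not performance
on motion-contaminated or low-SNR recordings.

`generateTrajectory()` produces pose-estimation-style keypoint tables
in which the animal dwells near each object in exactly the geometry
the exploration criteria demand, so the behavior module recovers the
scheduled exploration seconds to within one frame duration.

# Behavior scoring

A frame counts as investigating an object iff the nose is within 2 cm
of it, the body-center→nose axis points at the object within a 45°
half-angle — the facing criterion is not quantified in the original
task description, so the half-angle is exposed and reported — and the
body center is not over the object footprint (climbing exclusion; the
4 cm stand is simplified to a 2-cm-radius disc). The discrimination
index is $(t_{novel} - t_{familiar}) / (t_{novel} + t_{familiar})$;
trials with under 2 s total investigation, a single explored object in
the testing phase, or no learning-phase exploration are excluded.
Frames with pose likelihood below `likelihood_min` (default 0.6) are
non-exploratory, and more than 20% missing frames is an error.

# Numerical and design notes

* Pixel indices are 0-based row-major in all exported tables; time of
  frame $k$ (0-based) is $k/\mathrm{fps}$; all windows are half-open
  $[start, end)$.
* Frame rate and pixel size are required metadata — TIFF tags are
  unreliable across microscopes, so absence is an error, not a guess.
  Movies written by the package carry a YAML sidecar with the metadata
  and, for floating-point data, a power-of-two intensity scale (the
  scale changes only the exponent, so quantization is that of 32-bit
  float); integer movies round-trip bit-exactly through 16-bit TIFF.
* CSV floats are written at 9 significant digits so identical runs are
  byte-identical and diffable; one run seed expands into fixed
  per-stage substreams.
* Onset latency uses a strict crossing and frame resolution; the
  latency used for recovery scoring against planted onsets is the
  unsmoothed rise start (last sub-threshold frame before the first
  active frame), since centered smoothing shifts apparent onsets about
  two frames early.
* Degenerate inputs are defined, not accidental: zero-SD pixels are
  never active; zero-variance ANOVA comparisons are removed with
  $p = 1$; zero-baseline-SD traces fall back to an absolute prominence
  floor; zero-variance synchrony pairs are flagged and excluded.

# Worked example

```{r example, eval = FALSE}
truth <- randomSyntheticTruth(seed = 42)   # the default study conditions
movie <- generateMovie(truth)$movie
det <- detectMicrodomains(movie, detectionParams("invivo-astro"))
rec <- evaluateRecovery(det$rois, truth, movie)
c(precision = rec$precision, recall = rec$recall,
  onset_err = rec$median_abs_onset_error_s)

traces <- extractDff(movie, det$rois)
events <- buildEventTable(traces)
head(events)
```

The test suite runs these recovery experiments over 20 movies at the
default conditions (its own choice of problem size), plus a
1000-repeat type-I calibration of the ANOVA filter and a
100,000-sample Monte-Carlo check of the amplitude model; no empirical
number is claimed here that those tests and `scripts/acceptance.R` do
not themselves compute.

# Known limitations

* Detection is 2D per plane; no volumetric grouping.
* Movies are assumed motion-corrected and registered.
* Mixed-effects modeling and post hoc testing are out of scope: the
  exported tidy tables (one row per ROI/event/pair) are designed to be
  fed to `lme4`/`multcomp` or similar.
* The rise-time operationalization and the ANOVA sample unit are
  documented interpretations of under-specified criteria; both are
  isolated behind parameters and tested properties rather than buried
  in code.
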