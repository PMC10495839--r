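---
title: "Detecting capillary stalls in angiographic time series"
author: "capstall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting capillary stalls in angiographic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capstall)
```

## The problem

Capillary stalls are brief interruptions of red blood cell (RBC) flow in
single cortical capillaries. In plasma-labeled two-photon angiography the
dye fills the plasma, so vessels appear bright while unlabeled RBCs appear
as dark moving shadows inside the lumen. A stall is operationally defined
as the *same* shadow pattern remaining stationary for **two or more
consecutive frames**; during normal flow, at volume rates below ~1 Hz and
flow speeds of order mm/s, completely new shadows occupy the capillary in
every frame.

Manually scanning hundreds of capillaries across a 10-minute, 350-frame
record is slow (hours per dataset) and observer-dependent. capstall
implements the semi-automated alternative: extract a centerline per
capillary from a single click, build a motion-stabilized length–time (LT)
image (a kymograph: intensity along the capillary versus frame), and use
the **frame-to-frame Pearson correlation of consecutive LT rows** as a
stall score. Flowing frames decorrelate; frozen frames correlate. The
correlation trace is thresholded to flag candidate stalls, which are then
assembled into a *stallogram* (capillaries × frames boolean matrix) and
summarized by the field's standard statistics:

* **incidence** — % of counted capillaries that stall at least once;
* **point prevalence** — time-averaged % of capillaries simultaneously
  stalled;
* **cumulative stall duration** — mean % of the record that a stalling
  capillary spends stalled.

Everything is validated against a synthetic-data generator with exact
ground truth, so each stage is testable without imaging data.

## The detection model

For capillary $i$ with LT matrix $V \in \mathbb{R}^{T \times L}$ (row =
frame, column = position along the centerline), the correlation trace is

$$ r_t = \mathrm{corr}(V_{t,\cdot},\, V_{t+1,\cdot}), \qquad
   t = 1, \dots, T-1 . $$

A correlation is a property of a frame *pair*: $r_t \ge \theta$ marks
both frames $t$ and $t+1$ stalled, so the smallest event spans 2 frames —
one frame interval, 1.75 s at the 0.57 Hz acquisition this package
defaults to. Rows with zero variance correlate as 0 (a blank row carries
no evidence of a frozen pattern) and are flagged.

The default threshold $\theta = 0.4$ is deliberately low, trading
specificity for sensitivity, matching how the method is used with a human
reviewer downstream: false positives are cheap to reject by eye, missed
stalls are gone forever.

### Detrending

LT rows share static structure — end tapers, brightness variation along
the lumen — that correlates consecutive rows even during vigorous flow
and carries no information about stalling. The pipeline therefore
subtracts each column's temporal mean before correlating
(`detrend_lt()`), leaving only the per-frame shadow fluctuation. The
trade-off: a capillary stalled for most of the record resembles its own
temporal mean, loses contrast against it, and can be missed. With
typical stall durations of a few frames this regime is rare, but it is a
real limitation for permanently plugged vessels (which are better found
as persistently dark segments, a different analysis).

### Automated review

Fully automatic operation needs a surrogate for the human confirmation
step. Chance suprathreshold runs are common: a shadow profile is smooth
(RBC-scale, σ ≈ 3 µm ≈ 2 px), so an LT row of $L$ pixels has only about
$L/5$ effective degrees of freedom and the flowing-pair correlation has a
standard deviation of 0.2–0.3 for short capillaries. Over ~350 frame
pairs, single lucky pairs at $\theta = 0.4$ are near-certain.

`review_events()` confirms a flagged event only if

1. it spans at least `review_min_frames` (default 4) frames, **and**
2. some window of `review_min_frames` consecutive frames within it has
   **all pairwise** row correlations ≥ `review_pair_threshold`
   (default 0.5).

Rule 2 is the direct transcription of the stall definition — the *same*
shadows present throughout the event. A chance run arises from one lucky
consecutive pair; mutually correlating every pair of rows in a window is
orders of magnitude rarer. On kymograph-level simulations this rule keeps
95–100% of true stalls of ≥ 4 frames while reducing the false-positive
rate per flowing capillary from ~1 to below 0.15 even for 30-pixel
centerlines (0 for ≥ 50 px). The cost, stated plainly: true stalls of 2–3
frames are not confirmable by this rule and are only recovered in
workflows with an actual human reviewer (`review_min_frames = 2` disables
the filter; `export_candidates()` writes the flag list for external
review).

## Centerline extraction

The temporal mean image (shadows average out, lumen SNR is maximal) is
enhanced with a multiscale Hessian tubularity (Frangi) filter at scales
{1, 2, 3, 4} px — covering capillary radii of roughly 1.4–5.6 µm at
1.39 µm/px — thresholded (Otsu by default), thinned to a 1-px skeleton
(Zhang–Suen with staircase cleanup; genuine branch points are not
8-simple and survive the cleanup), and converted to a graph whose nodes
are endpoints/branch points and whose edges are the degree-2 pixel paths
between them. A user click selects the nearest edge (ties broken by
lowest edge id; clicks farther than 20 px are rejected). Centerlines of 5
pixels or less are excluded — too short for a meaningful row correlation.

## Motion stabilization

A crop around each centerline (margin 10 px) is registered across time by
translation-only FFT cross-correlation with quadratic subpixel peak
interpolation, against the temporal-mean crop (two passes: the raw mean
is blurred by the motion itself, so the motion-compensated mean is
re-derived and registration repeated). Because the moving shadows drag
the correlation peak along the vessel axis, the offset trajectory is
smoothed with a 5-frame running median — tissue motion is slow, shadow
jitter is white. Rotation and non-rigid deformation are out of scope:
crops are small and cortical motion at this scale is predominantly
translational.

## Stall statistics and the incidence model

`compute_statistics()` implements the three summary statistics with the
count of *all* analyzed capillaries as denominator (for real data the
denominator — capillaries with clear RBC contrast — is a human judgment
and is user-supplied). Point prevalence averages over frames.
`filter_min_duration()` removes events shorter than a cutoff
(`min_frames = 2` keeps everything); at the default frame period a
5-frame cutoff keeps only stalls of ≥ 8.8 s, the "long stall" regime
comparable to slower modalities such as OCT angiography.

Incidence as a function of measurement time is fit with

$$ I_{\text{stall}}(t) = A\,(1 - e^{-B t}) + C, $$

$t$ in minutes ($B$ in 1/min: published fits of $B \approx 6.4$ saturate
within ~30 s, which matches the observed curve shape; the alternative —
$t$ in seconds — would saturate in a fraction of a frame). The saturating
form expresses that a consistent subset of capillaries stalls repeatedly
rather than stalls being spread uniformly over the network. Fitting is
Levenberg–Marquardt least squares with three starts (the user's
initialization plus two data-driven ones); a constant curve is flagged
degenerate ($A = 0$, $C$ = mean, $B$ unidentifiable) rather than fit.

## Vessel dynamics

Arteriole diameter is the full width at half maximum of the min–max
normalized average of 20 intensity profiles drawn perpendicular to the
vessel axis, 2 µm apart, sampled at 0.5 µm with linear interpolation of
the half-max crossings. ΔF/F uses the ROI-mean intensity with the 10th
percentile of the trace as baseline $F_0$ — robust to dilation
transients; the paper-style alternative (mean of a quiescent period)
requires manual annotation. "Large" dilations are local maxima of the
fractional increase over a 31-frame rolling-median baseline exceeding 10%
(both choices configurable; no published definition exists to inherit),
and any qualifying peak with another within 10 frames (17.5 s) is
excluded — both drop — to avoid overlapping responses.
`triggered_average()` then averages the stall point-prevalence trace in
±10-frame windows around each peak (lag 0 = peak diameter), with
event-wise standard errors.

## The synthetic-data generator

`simulate_angiogram()` renders what the analysis consumes:

* capillaries as smooth random curves (bounded curvature, minimum mutual
  separation of 3 tube widths so skeletons never merge), Gaussian tube
  cross-section of FWHM 6 µm, amplitude 0.6 over a 0.15 background;
* RBC shadows as multiplicative Gaussian dips (σ = 3 µm, depth 0.55,
  mean 8 shadows per 100 µm) at positions redrawn independently every
  flowing frame — at 0.57 Hz and mm/s speeds a shadow crosses the whole
  capillary between frames, so advection is unobservable and independent
  redraws are the faithful model — and frozen throughout each stall;
* stalls from a discrete alternating renewal process: per-frame onset
  hazard $1 - e^{-\lambda \Delta t}$ with λ = 0.8 events/capillary/min
  for an eligible 30% of capillaries, durations 2 + Geom(0.25) frames
  (mean ≈ 5 frames ≈ 8.8 s). No published generative stall model exists;
  these rates were chosen once to land the summary statistics in the
  observed in-vivo range (incidence ~30%, stalled fraction of a stalling
  capillary ~10% of the record, aged-cohort-like) and are not tuned;
* smooth rigid whole-field motion (peak 2 px), additive Gaussian noise
  (sd 0.05), 16-bit quantization (so TIFF round trips are bit-exact);
* optionally an arteriole with logistic-edged cross profile whose width
  follows a diameter trace containing isolated dilation bumps and whose
  brightness is linearly coupled to fractional diameter change.

Default geometry mirrors the reference acquisition: 512×512 px over
713×713 µm (1.393 µm/px), 350 frames at 0.57 Hz (1.754 s/frame).

What the generator deliberately does **not** emulate: optical PSF and
depth effects, photobleaching, shot (Poisson) noise statistics, vessel
crossings and diving segments, flow-speed heterogeneity, and shadows
advecting visibly between frames (relevant only at much higher frame
rates). Passing tests on this generator therefore demonstrate the
*algorithmic* correctness and the detector's behavior under the stated
phenomenology — not performance on real microscopy, where segmentation
quality and human capillary selection dominate.

## Numerical choices and degenerate inputs

* Pearson correlation of a zero-variance row is defined as 0 and flagged.
* Registration requires a crop of at least 8×8 px; sub-pixel offsets come
  from a quadratic fit to the 3×3 correlation peak, clamped to ±0.5 px.
* LT samples falling outside the frame take the nearest edge value and
  are counted (`n_clamped`).
* FWHM requires both half-max crossings to be bracketed; per-frame
  failures yield `NA` and are counted rather than propagated as errors.
* Ties in click selection go to the lowest edge id; all orderings
  (nodes, edges) are deterministic, and all simulator output is a pure
  function of `(config, seed)`.
* Stallogram CSVs and all file outputs use 0-based frame/pixel indices;
  the R API is 1-based.

## Test problem sizes

The test suite exercises the full chain at reduced sizes chosen to keep a
complete run comfortably interactive: detector characterization at
256×256 px / 200 frames / 25 capillaries, and one full-geometry
end-to-end run at 512×512 px / 350 frames / 50 capillaries. Statistical
checks against the renewal-process oracle use 200 independent seeds of
the image-free stall process.

## Known limitations

* Long-duration stalls (most of the record) lose contrast after
  detrending and can be missed (see above).
* Capillaries under ~40 px remain the hardest case for human-free
  operation; their confirmed false-positive rate is small but nonzero.
* The vessel graph has no notion of vessel identity across branch
  points; a click selects a branch-to-branch segment, not an anatomical
  vessel.
* Registration is translation-only and per-capillary; strong rotational
  or non-rigid motion would require a different model.
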