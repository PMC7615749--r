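---
title: "Models and methods behind gliovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gliovasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gliovasc` analyses two-channel two-photon time-lapse recordings of cortical
penetrating arterioles and the astrocytes that enwrap them: a vascular
channel (intravascular dye) carries the vessel geometry, an activity channel
(a Ca²⁺ indicator such as OGB-1) carries somatic and endfoot Ca²⁺ dynamics.
The pipeline produces a vessel diameter time series with peak and
area-under-curve (AUC) response metrics, per-ROI Ca²⁺ transient tables, and
an angle×time kymograph of endfoot ΔF/F with event calls. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where the method left room.

All coordinates are 0-based `(row, col)` with the origin at the centre of
the top-left pixel; frames are 0-based and time is `frame * frame_interval`
seconds. Angles are integer degree bins 0–359 with the bin centre at the bin
value, angle 0 along the +column axis, counter-clockwise.

## The synthetic recording generator

No public raw recordings exist for this kind of experiment, so every stage
is validated against `simulate_movie()`, which renders a scene with complete
ground truth:

* a **penetrating arteriole** as an anti-aliased bright disc whose per-frame
  diameter follows a prescribed fractional dilation profile
  (`dilation_pulse()` defaults to a ~1 min stimulus reaching +36 %, the
  typical magnitude of a hypoxia-evoked dilation). Anti-aliased
  (area-weighted) edges keep diameter recovery testable to sub-pixel
  accuracy — hard edges would quantize the achievable tolerance;
* an **endfoot annulus** with a Gaussian radial cross-section (FWHM
  `endfoot_thickness`) riding at `lumen radius + endfoot_gap +
  thickness/2`, deforming with the vessel; scheduled endfoot events
  multiply the annulus brightness over an angular span with
  instantaneous-rise/exponential-decay kinetics;
* **somata** as anti-aliased discs whose intensity follows
  `baseline * (1 + ΔF/F(t))`, with per-ROI Poisson-scheduled,
  non-overlapping transients (instantaneous rise, exponential decay with
  `transient_decay_tau`, truncated at the scheduled offset);
* a **static background texture** (`texture_sd`): a spatially smooth random
  field drifting rigidly with the scene. This emulates the out-of-focus
  capillaries and plasma fluorescence that pervade real vascular-channel
  images and that rigid registration actually locks onto — a bare
  rotationally symmetric dilating tube leaves translation ill-constrained,
  which is an artefact of idealized scenes, not of real data. The activity
  channel receives a 0.3× weaker copy, since indicator-stained neuropil is
  comparatively diffuse;
* **rigid drift**: a low-pass-filtered random walk anchored at frame 0 and
  scaled to `drift_amplitude`, applied identically to both channels, with an
  integer-only mode for exact registration checks;
* **noise added last**: Gaussian with SD `noise_sigma`, plus an optional
  Poisson component via `photon_gain` (off by default so that variance
  accounting stays exact).

Defaults are 256×256 px, 300 frames at 1 Hz, 0.25 µm/px, lumen radius 16 px
(an ~8 µm resting arteriole, matching typical penetrating-vessel calibres,
sampled finely enough that ±3-percentage-point peak recovery is meaningful
against the 1 px quantization of a segmented boundary). Structure (drift,
geometry, schedules) and noise draw from separable RNG streams (`seed`,
`noise_seed`), so one scene can be re-rendered under independent noise.

What the generator deliberately does **not** model: capillary networks,
red-blood-cell shadows, Z-drift, bleaching, indicator re-distribution, or
neuropil Ca²⁺ waves. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not robustness to every artefact of
in vivo data.

## Rigid motion correction

The template is the pixel-wise mean of the first 20 vascular frames.
Per-frame translation is estimated by cross-correlation in the Fourier
domain, refined to 0.1 px with a locally up-sampled DFT (×10 by default;
`upsample = 1` gives whole-pixel estimates). Both channels are warped with
the vascular-channel shifts via bilinear interpolation; exposed edge pixels
are filled with the template mean and flagged in a validity mask rather than
cropped.

Two choices deserve note. First, shifts are **re-referenced to frame 0**:
a template averaged over frames that themselves drift sits at the mean early
position, so raw template-relative shifts carry an arbitrary constant
offset; anchoring at the first frame makes trajectories comparable across
runs and against ground truth. Second, `n_passes = 2` optionally rebuilds
the template from the aligned first frames and re-estimates once, removing
the blur a drifting template window causes; with integer drift this makes
recovery exact.

## Two-step truncated-SVD patch denoising

Each channel is split into overlapping 8×8 px patches (stride 4 px, so 50 %
overlap; border patches are anchored to the frame edge so coverage is
complete). Each patch is serialized to a 64×T matrix (pixel time courses in
rows) and replaced by its best rank-`rank1` approximation (Eckart–Young).
The retained temporal singular vectors of all patches in a larger window
(4×4 patches = 32×32 px), weighted by their singular values, are stacked and
approximated by a second truncated SVD of rank `rank2`; each patch's
temporal components are projected onto that shared basis, patches are
reconstructed, and overlapping estimates are averaged.

The ranks are tunable (`rank1 = 4`, `rank2 = 8` by default) because the
right values depend on how many independent temporal processes a patch can
see; the defaults comfortably hold one vessel edge plus one or two Ca²⁺
sources per patch. Weighting the second stage by singular values makes the
shared basis favour high-energy temporal modes; the unweighted variant
differs only in how aggressively weak modes are pruned. The operator is
scale-equivariant, independent of patch enumeration order, and exactly the
identity on input whose global rank is at most `min(rank1, rank2)` — these
invariants are enforced by tests.

## Vessel diameter via Chan–Vese active contours

The lumen is segmented by a two-phase, region-mean Chan–Vese evolution
(morphological level-set implementation: the data term attaches pixels to
the inside/outside mean intensities; the contour-length penalty is realized
by alternating sup-inf/inf-sup smoothing sweeps). The contour is initialized
from an intensity threshold in a band around a user-supplied line scan
(matching the manual line-drawing step of the original workflow) or, for
temporal coherence, from the previous frame's mask. Constraints applied
after evolution: hole filling, restriction to the single connected component
intersecting the line, and a ±30 % per-frame area-change cap (excess flags
the frame invalid and carries the previous mask forward) — these stabilize
the segmentation against dye-intensity flicker.

Diameter is the length of the longest contiguous run of the mask sampled
bilinearly along the line at 0.25 px steps. A segmented binary boundary
quantizes each edge to the pixel grid, so single-frame diameters carry up to
±0.5 px per edge; `response_metrics()` therefore applies a 3-frame running
median (configurable, `median_filter = 1` disables) before computing
metrics. A full-width-at-half-maximum estimator (`diameter_fwhm()`) is
provided as an independent cross-check; on clean discs the two agree within
1 px.

Response metrics use the fractional change `f(t) = (d(t) − d̄_base)/d̄_base`:
`peak_percent = 100·max f` over the response window, and
`auc = ∫f dt / window duration`. Normalizing the AUC by window duration
makes values comparable across recordings of different lengths, but the
scale is a convention — only relative comparisons between conditions are
meaningful.

## Somatic Ca²⁺ transients

Cell bodies are found on the temporal mean of the activity channel by a
local-mean adaptive threshold (window ≈ 2× the expected soma diameter),
hole-filled, filtered by area, and cleaned of anything touching the vessel
lumen (dilated to cover the perivascular ring). Components larger than
twice the median detected soma area (or the upper area bound) are split by
a watershed on the distance transform, separating somata merged by blur.
Detected masks can be replaced or edited via a user-supplied label image —
the manual-curation hook.

Per ROI, ΔF/F uses `F0 = median` of the baseline window (a
percentile-of-whole-trace alternative is available). Transients are maximal
runs of at least 3 consecutive frames in which the Gaussian-smoothed
(σ = 1 frame) ΔF/F exceeds 2.5 robust SDs. The robust scale is
`1.4826 × MAD` (Gaussian-consistent) of the **raw** baseline ΔF/F, not of
the smoothed trace: smoothing leaves the noise strongly autocorrelated, so
thresholding a smoothed trace at multiples of its *own* SD admits chance
3-frame runs at a rate (~0.1 per 300-frame recording) that would make the
nominal 2.5-SD level misleading; scaling by the raw-trace SD keeps the
false-event rate effectively zero while leaving slow, genuine transients —
which survive smoothing almost unattenuated — detectable at
signal-to-noise ≥ 5 with precision and recall above 0.95. Degenerate
noiseless traces (MAD = 0) are flagged and fall back to a zero threshold.
Event boundaries are reported at the smoothed trace's threshold crossings;
no sub-frame refinement is attempted.

Note one subtlety of run-based event semantics: *raising* the threshold can
split one suprathreshold run into two, so event **counts** are not monotone
in the threshold. The monotone facts — the suprathreshold set shrinks and
every higher-threshold event nests inside a lower-threshold one — are what
the property tests assert.

## Endfoot tracking and kymograph

Frames are cropped around the vessel centre (per-frame lumen centroids from
the diameter stage, or a fixed user-supplied centre), ridge-enhanced with a
multi-scale Hessian-eigenvalue filter (scales 1, 2, 4 px, γ-normalized
`s²·max(−λ₂, 0)` response), and resampled to polar coordinates (radii
1..`r_max` in 1 px steps, 360 one-degree columns, bilinear). The endfoot
circumference is the minimal-cost path through the graph of per-column
ridge local maxima: edges connect nodes in adjacent columns with
|Δr| ≤ 2 px, costed by `(max ridge − node ridge) + 0.5·|Δr|`; the path must
close (|r(0) − r(359)| ≤ 2 px) and its total length Σ|Δr| is capped at
`2·r_max`. With a previous-frame path the search is confined to a ±5 px
band around it, which keeps the tracker on the same annulus when several
concentric structures are present; an infeasible frame is flagged and the
previous path carried forward. The cap and the band are free parameters of
the method — nothing in the underlying procedure pins them — and are
exposed in the configuration.

The kymograph samples the raw activity intensity in a ±2 px radial band
around the tracked path, one 360-vector per frame, and converts to ΔF/F
against a **per-angle** baseline-window median (a global baseline is
available; per-angle absorbs the static brightness profile around the
circumference). Events are connected components of `ΔF/F > 0.05` under
8-connectivity with a periodic angle axis (degree 359 adjacent to 0, so an
event straddling the seam is one event), kept when their area **strictly
exceeds** 64 cells (frames × degrees). The per-frame maximal projection
along angles gives the endfoot Ca²⁺ trace.

Known limitation: during large dilations the sampling band sweeps across
static background structure, leaving residual baseline shifts of a few
percent ΔF/F in the upper tail that no per-angle baseline can remove. The
5 %/64-cell event rule tolerates them (event-free dilating recordings yield
zero event calls), but kymographs of strongly dilating vessels should be
read with this in mind.

## Summaries

`summarize_recording()` aggregates stage outputs — never recomputing them —
into per-recording scalars (vessel peak %, AUC, responder fractions) and
tidy one-row-per-unit tables keyed by recording identifiers, ready for
nested mixed-effects modelling in external tools, which is where that
analysis belongs. Because the scalar a scatterplot of "Ca²⁺ response vs
dilation" should use is underdetermined, three per-ROI response scalars are
exported (event count, peak ΔF/F, summed positive ΔF/F area);
`correlate_responses()` reports Pearson and Spearman coefficients with
two-sided p-values and refuses zero-variance input.

## Numerical and testing choices

Degenerate inputs are handled explicitly: all-zero frames return a zero
shift with a warning; empty lumen intersections and frames failing the
area-change cap are flagged invalid (a recording with >50 % invalid frames
is an error); MAD = 0 traces are flagged degenerate; ridge maps without
signal mark the frame infeasible.

Verification runs at two scales. Unit tests use small scenes (96–160 px,
30–120 frames) where every stage finishes in seconds; the end-to-end
accuracy checks use the study-scale default (256×256×300, drift up to
10 px, 20 movies for registration) plus analytic fixtures with closed-form
answers (disc chords, diagonal singular values, triangular response pulses,
seam-straddling components). Every detector is checked against an
independent oracle written as a naive enumeration: brute-force maximal-run
scanning for transients, fixpoint label propagation for connected
components, and the Eckart–Young identity for the SVD stages. The
`scripts/acceptance.R` script re-derives the headline quantities
(registration RMS, denoiser MSE ratio, peak-dilation recovery, detector
precision/recall and null rates, endfoot path RMS and event recall) from
fresh simulations under a caller-supplied seed.
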