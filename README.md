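# gliovasc

Analysis pipeline for two-channel two-photon time-lapse recordings of
cortical penetrating arterioles and perivascular astrocytes, plus a
synthetic-movie generator with complete ground truth so that every stage of
the pipeline can be verified quantitatively.

In these experiments one channel carries an intravascular dye (vessel
geometry) and the other a Ca²⁺ indicator (astrocyte activity). The
scientific readouts are:

* **vessel diameter over time** and its stimulus response — peak fractional
  change and normalized area under the curve (AUC) of
  `f(t) = (d(t) − d̄_baseline)/d̄_baseline`;
* **somatic Ca²⁺ transients** — maximal runs of ≥ 3 consecutive frames in
  which Gaussian-smoothed (σ = 1 frame) ΔF/F exceeds 2.5 robust standard
  deviations (1.4826 × MAD of the baseline);
* **endfoot Ca²⁺ events** — the astrocyte endfoot encircling the vessel is
  tracked as a closed minimal-cost path in polar coordinates
  (`φ = 0..359°`, origin at the vessel centre) through a ridge-enhanced
  image; ΔF/F sampled along the tracked circumference forms a 360 × T
  kymograph in which events are 8-connected components (periodic angle
  axis) above 5 % ΔF/F and larger than 64 cells (frames × degrees).

The stages are: rigid motion correction against a 20-frame average template
(Fourier cross-correlation, 0.1 px sub-pixel refinement) → two-step
truncated-SVD patch denoising (8×8 px patches, second SVD over larger
windows of temporal singular vectors, overlap averaging) → Chan–Vese
active-contour lumen segmentation along a user-drawn line scan →
MAD-thresholded transient detection → polar endfoot tracking and kymograph
event detection → tidy per-vessel/per-ROI tables ready for mixed-model
analysis elsewhere.

## Worked example

Simulate a recording of an ~8 µm arteriole dilating by 36 % during a
one-minute stimulus, with four astrocyte somata and scheduled endfoot
events, then run the full pipeline:

```r
library(gliovasc)

params <- sim_params(height = 160, width = 160, n_frames = 120,
                     n_somata = 4, soma_radius_range = c(10, 14),
                     dilation_profile = dilation_pulse(120, onset = 40,
                                                       rise = 15, plateau = 20,
                                                       fall = 30, peak = 0.36),
                     seed = 42)
sim <- simulate_movie(params)
sim$movie
#> <two_channel_movie> 160 x 160 px, 120 frames
#>   pixel size 0.25 um/px, frame interval 1 s
#>   channels: vascular, activity

line <- line_scan(c(79.5, 51.5), c(79.5, 107.5))  # across the vessel
res <- run_pipeline(sim$movie, line,
                    pipeline_config(stimulus_window = c(40, 119),
                                    soma_diameter = 24))
res$summary
#> <recording_summary> recording
#>   vessel: peak +37.5%, AUC 0.1972
#>   somata: 4 ROIs, 7 events, responder fraction 1
#>   endfoot events: 2
```

The recovered peak (+37.5 %) sits within the segmentation quantization of
the true +36 % profile; the AUC is the duration-normalized integral of the
fractional diameter change over the stimulus window. `res$diameter` holds
the per-frame trace, `res$soma$events` the transient table (onset, offset,
peak ΔF/F per ROI), `res$kymograph` the 360 × T endfoot ΔF/F matrix, and
`write_pipeline_outputs(res, dir)` exports everything as tidy CSV/JSON with
a manifest. A thin command-line wrapper is available in `exec/gliovasc`
(`simulate`, `register`, `pipeline` subcommands).

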