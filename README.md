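# capstall

Semi-automated detection and analysis of **capillary stalling** —
transient interruptions of red blood cell (RBC) flow in single cortical
capillaries — from 2D+time fluorescence angiography.

In plasma-labeled two-photon angiograms, vessels are bright and unlabeled
RBCs appear as dark shadows. During a **stall**, the same shadows stay
frozen in place for two or more consecutive frames; during flow, new
shadows occupy the capillary in every frame. capstall turns that
observation into an analysis chain:

1. **Centerlines** — multiscale Hessian (Frangi) vessel enhancement on
   the temporal mean image, Otsu segmentation, morphological thinning,
   skeleton-to-graph conversion, and nearest-edge selection from a single
   click per capillary.
2. **Kymographs** — per-capillary motion stabilization (FFT
   cross-correlation, subpixel) and extraction of the length–time (LT)
   image `V[t, s]` (frame × position along the centerline).
3. **Detection** — the frame-to-frame Pearson correlation
   `r_t = corr(V[t,·], V[t+1,·])` rises sharply while the shadow pattern
   is frozen. Thresholding `r_t ≥ θ` (default θ = 0.4, deliberately low)
   flags stalled frame pairs; an automated review rule confirms events in
   human-free operation.
4. **Statistics** — the stallogram (capillaries × frames), stall
   incidence, point prevalence, cumulative stall duration, duration
   filtering and CDFs, incidence versus measurement time and its
   saturating exponential model `I(t) = A(1 − exp(−Bt)) + C`, and
   validation truth tables (sensitivity/specificity).
5. **Vessel dynamics** — arteriole diameter by profile FWHM, ΔF/F,
   isolated-dilation detection, and dilation-triggered averages of stall
   prevalence.
6. **Simulator** — a synthetic angiogram generator with exact ground
   truth (centerlines, stallograms, motion, arteriole dynamics) so every
   stage is testable without imaging data.

See the vignette (`vignettes/capillary-stalling.Rmd`) for the model,
parameter choices, and limitations.

## Worked example

Simulate a small field, run the full pipeline with clicks at the true
capillary midpoints, and compare against ground truth:

```r
library(capstall)

cfg <- simulation_config(height_px = 256, width_px = 256,
                         n_frames = 200, n_capillaries = 25, seed = 101)
sim <- simulate_angiogram(cfg)

clicks <- do.call(rbind, lapply(sim$truth$centerlines, function(cl) {
  p <- cl$points[round(cl$length_px / 2), ]
  data.frame(capillary_label = cl$capillary_id, x = p[1], y = p[2])
}))

ext <- extract_centerlines(sim$stack, clicks)
pl  <- run_stall_pipeline(sim$stack, ext$centerlines)
pl
#> <stall_pipeline> 25 capillaries, 23 confirmed events (489 flagged)
#> <stall_statistics> incidence 48.00%, point prevalence 3.380%,
#>   cumulative stall duration 7.04% (12/25 capillaries stalling)

truth_ids <- vapply(sim$truth$centerlines, `[[`, character(1), "capillary_id")
truth_sub <- stallogram(
  sim$truth$stallogram$matrix[match(pl$stallogram$capillary_ids, truth_ids), ],
  pl$stallogram$capillary_ids, cfg$frame_period)
compare_to_truth(pl$stallogram, truth_sub)
#> <confusion_table>
#>   ground truth positive (12):   0.0% negative (0)  100.0% positive (12)
#>   ground truth negative (13): 100.0% negative (13)    0.0% positive (0)
```

Reading the output: 489 frame-pair candidates were flagged at the low
threshold, the automated review confirmed 23 events, and all 12 truly
stalling capillaries were recovered with no false-positive capillaries.
Incidence (48%) is the percent of analyzed capillaries with at least one
confirmed stall; point prevalence (3.4%) is the average percent stalled
at any instant; cumulative stall duration (7.0%) is the average fraction
of the record a stalling capillary spends stalled.

(Numbers above are from this exact script; they are deterministic given
the seed.)

## Command line

A thin CLI over the same functions lives at `inst/cli/capstall.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","capstall.R",package="capstall"))')" \
    run-all --seed 1 --out out/
```

Subcommands: `simulate`, `centerlines`, `kymo`, `detect`, `stats`,
`dynamics`, `validate`, `run-all`. All file outputs (stallogram CSV,
events CSV, statistics/confusion JSON, 16-bit multipage TIFF) use
0-based frame and pixel indices.

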