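# sparkquant

Image quantification for **separation-of-phases kinase activity reporters
(SPARK)** and their single-channel dual Ca²⁺/kinase variants.

SPARK reporters condense into bright, near-spherical droplets when their
target kinase (here AMPK, the cellular energy-stress sensor) is active:
phosphorylation drives multivalent binding between the two reporter
halves and the reporter demixes from the diffuse cytosolic pool. Kinase
activity is read out as the number and size of droplets per cell over
time. In the dual GCaMP-based variant one green channel carries two
signals: overall cytosolic brightness reports Ca²⁺, droplet count reports
kinase activity.

The package is for experimenters and image analysts who need these
readouts as reproducible, scriptable computations rather than interactive
point-and-click steps:

- **Droplet counting** in time-lapse movies by topographic prominence —
  a maximum counts if the intensity drops by at least a stated prominence
  on every path to a higher maximum — verified against a brute-force
  oracle, with deterministic plateau and tie handling.
- **Dual-threshold counting** for the single-channel dual reporter: a
  high intensity floor while Ca²⁺ is elevated, a low one at rest, merged
  by a reproducible Ca²⁺ gate (both raw traces are kept for audit).
- **Histogram auto-thresholds**: Kapur maximum-entropy
  (argmax over levels of the summed background/foreground Shannon
  entropies) and the geometric Triangle method (bin at maximal
  perpendicular distance from the histogram's peak-to-tail chord).
- **Rolling-ball background subtraction** (grayscale opening by a
  non-flat ball), pixel-wise self-multiplication, 8-bit rescaling,
  per-frame display normalization.
- **3D condensate segmentation and morphometry** on anisotropic voxel
  grids: 26-connected labelling, voxel-count and flux-conserving volumes,
  surface area by normal-corrected face projection, and sphericity
  Ψ = π^{1/3}(6V)^{2/3}/A.
- **Cell typing** by largest-droplet equivalent diameter
  (type 1 < 1.0 µm ≤ type 2 ≤ 3.6 µm < type 3) with population
  summaries in the *n = replicates/cells* convention.
- **Dynamic readouts**: formation latency (sustained-count onset rule),
  washout dispersion fraction, integrated Ca²⁺ intensity traces,
  per-cell heatmap normalization.
- **A synthetic microscopy generator** with exact ground truth — droplets
  nucleate (Poisson), grow, coalesce volume-conservingly and dissolve
  under a kinase-activity trace, with flux-conserving rendering and
  Poisson + Gaussian noise — used to validate the whole pipeline end to
  end.

## Worked example

Simulate a dual-reporter movie (one cell, 60 frames at 5 s; Ca²⁺
elevated 3× during frames 11–44; kinase activity switching on 3 frames
after stimulus onset; 14% of droplets persistent), then quantify it:

```r
library(sparkquant)

scene <- demo_scene(seed = 42)
sched <- do.call(simulate_droplet_kinetics,
                 c(list(scene$protocol, scene$config), scene$kinetics))
rend  <- render_movie(sched, scene$protocol, scene$config,
                      gcamp_mode = TRUE)

bg        <- roi_rect(1:4, 1:4, c(64, 64), "background")
mask      <- cell_footprint(scene$config, 1)
corrected <- subtract_background_roi(rend$stack, bg)
intensity <- gcamp_intensity_trace(rend$stack, mask, background_roi = bg)
gate      <- ca_gate_from_trace(intensity, baseline_frames = 1:10)
counts    <- dual_threshold_count(corrected, mask,
                                  low_thr = 150, high_thr = 450,
                                  prominence = 100, ca_gate = gate)
counts[12:17, ]
#>    frame time_s count_low count_high ca_gate count_merged
#> 12    12     55         1          0    TRUE            0
#> 13    13     60         1          0    TRUE            0
#> 14    14     65         1          1    TRUE            1
#> 15    15     70         1          1    TRUE            1
#> 16    16     75         2          2    TRUE            2
#> 17    17     80         4          4    TRUE            4

formation_latency(counts$count_merged, onset_frame = 11,
                  frame_interval_s = 5)
#> [1] 0.5        # minutes from stimulus onset to a sustained response

dispersion_fraction(counts$count_merged, peak_window = 11:44,
                    washout_window = 50:60)
#> [1] 100        # % of peak-count droplets gone after washout (this seed
#>                # happened to draw no persistent droplets)

all(counts$count_merged == rend$truth$counts$count)
#> [1] TRUE       # per-frame counts match the generator ground truth
```

The merged trace peaks at 14 droplets during stimulation. The latency of
0.5 min is the time for the third droplet to appear (the onset rule
requires ≥ 3 clusters for 2 consecutive frames), which includes the
generator's 3-frame activity lag.

For z-stacks:

```r
seg <- segment_stack(stack, rolling_radius_px = 10)
seg$clusters   # volume_um3, volume_flux_um3, sphericity, centroid, ...
```

`run_pipeline(pipeline_config(seed = 1), "out/")` drives the whole chain
and writes `traces.csv`, `cells.csv`, `summary.json` and a reproducibility
manifest; `inst/scripts/spark-quant` wraps it for the shell.

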