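---
title: "Quantifying phase-separation kinase reporters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phase-separation kinase reporters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparkquant)
```

## The measurement problem

Separation-of-phases activity reporters (SPARK) turn a kinase's activity
into a countable image feature: when the target kinase is active,
phosphorylation drives multivalent binding between the two reporter halves
and the reporter condenses out of the diffuse cytosolic pool into bright,
near-spherical droplets. Activity is then read out as the number and size
of droplets per cell over time. A dual variant replaces the fluorescent
protein with a single-FP Ca2+ sensor, so one green channel carries two
signals at once: overall cytosolic brightness tracks Ca2+, while droplet
count tracks kinase (AMPK) activity.

sparkquant implements the quantification side of such experiments as
testable, scriptable operations:

* droplet counting in time-lapse movies by topographic prominence;
* the dual-threshold procedure that disentangles the two signals of the
  single-channel dual reporter;
* the z-stack segmentation chain (rolling ball, self-multiplication,
  8-bit rescale, Triangle threshold) with 3D morphometry;
* largest-droplet cell typing and population summaries;
* per-cell dynamic readouts: formation latency, washout dispersion
  fraction, integrated Ca2+ traces, per-cell heatmap normalization;
* a synthetic microscopy generator with exact ground truth, used to
  validate everything above end to end.

## The synthetic scene model

Because the live-cell movies behind this class of experiment are rarely
deposited, the package ships a generator whose outputs stand in for them.
A scene is a set of elliptical cells with a diffuse cytosolic reporter
pool, imaged at a configured pixel size, frame interval and noise level.
Under an activity protocol `a(t)` in [0, 1] and a Ca2+ trace `c(t)`,
droplets:

* nucleate as a Poisson process with rate `nucleation_rate * a(t)` per
  minute, uniformly inside the cell footprint (optionally with a minimum
  separation, rejection-sampled);
* grow linearly in diameter at `growth_rate * a(t)`;
* dissolve, if not persistent, with per-frame probability
  `1 - exp(-dissolve_rate * (1 - a(t)) * dt)` — the contract fixes the two
  endpoints (full rate at `a = 0`, none at `a = 1`) and we interpolate
  linearly in between;
* coalesce when two centres come within the sum of their radii, into one
  droplet of volume-conserving diameter at the volume-weighted centre;
* a fraction `persistent_fraction` of droplets never dissolves, modelling
  the long-lived condensates that remain after stimulation as a memory of
  past activity.

**Droplet rendering.** Condensates are dense liquid droplets with an
approximately fixed internal reporter concentration, so they image as
flat-topped spots, not as Gaussian clouds. We render a droplet of diameter
`d` as a solid disk (2D) or ball (3D) with a PSF-blurred edge,
`pnorm((R - r) / sigma)`, whose full width at half maximum equals `d`.
Total droplet flux scales as `enrichment * expression * (pi/6) d^3` —
bigger droplets are brighter in proportion to their volume. The flat-top
choice matters quantitatively: with Gaussian-cloud droplets, any
histogram-foot threshold (which is where the Triangle method sits by
design) recovers volumes several-fold too large, and there is no level at
which a threshold reproduces the geometric diameter. With a flat top, the
half-maximum crossing sits at the true radius.

**Flux conservation.** Before noise, each cell's total reporter signal per
frame is exactly `expression * footprint pixels` (times `c(t)` in dual
mode): droplet fluxes are drawn out of the diffuse pool and the diffuse
level is what remains. This reproduces the cytosolic dimming seen when a
large fraction of the reporter condenses, and it is what makes the
integrated intensity trace a clean Ca2+ readout — condensation only
redistributes photons within the cell. A droplet population that would
drain more than 90% of the pool is capped at 90%, so the diffuse level
never goes negative.

**Noise.** Poisson shot noise (with a gain parameter, intensity units per
photon) followed by Gaussian read noise and a constant camera offset. The
generator does not model photobleaching, focus drift, cell movement, or a
realistic (Airy/Gibson-Lanni) PSF; passing tests on these scenes therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artifact of real acquisitions.

## Counting by topographic prominence

Interactive maxima counting depends on a hand-tuned noise tolerance. We
replace it with topographic prominence: a local maximum counts if the
intensity must drop by at least `prominence` on any path from it to a
higher maximum. Prominence has an exact definition, which makes the
counter verifiable — the test suite checks it against a brute-force flood
oracle on 1000 random images, demanding exact agreement. Plateaus count
once (their centroid is reported), and equal-height peaks are ordered
deterministically by raster index. The implementation floods the image
from above with a union-find structure, so prominence equals the
persistence of each peak's component.

On the synthetic movies, a prominence of 100 intensity units sits roughly
an order of magnitude above the shot-noise prominence scale and a factor
of a few below the faintest droplet's amplitude; the defaults were
calibrated on synthetic scenes only, since the original interactive
tolerances are not recoverable.

## The dual-threshold merge

With the dual reporter, elevated Ca2+ multiplies all reporter intensity,
so one absolute intensity floor cannot serve both Ca2+ states: a floor
high enough to reject the bright elevated-Ca2+ cytosol would miss droplets
at resting Ca2+. The published procedure counts twice — once with a high
and once with a low threshold — and merges the two traces by hand. We
automate the merge with a deterministic Ca2+ gate: frames whose integrated
cell intensity exceeds 1.5x the pre-stimulus baseline mean use the high
threshold, the rest the low one. Both raw traces are always returned so
the merge can be audited or redone manually. The gate factor of 1.5 sits
midway between the resting level (1.0) and the two-to-four-fold Ca2+
elevations typical of store-depletion stimuli.

## The z-stack segmentation chain

`segment_stack()` applies the published conditioning chain in order:

1. per-slice rolling-ball background subtraction — implemented as
   grayscale opening by a *non-flat ball* structuring element (the classic
   formulation), not a flat disk; the default radius should be several
   times the expected droplet radius so no droplet is flattened into the
   background;
2. pixel-wise self-multiplication — a monotone transform that stretches
   relative contrast before thresholding;
3. linear 8-bit rescale using the global stack minimum and maximum, so a
   single mapping produces the single stack histogram;
4. Triangle threshold on that histogram — the bin at maximal perpendicular
   distance from the peak-to-tail chord, on the longer-tail side;
5. 26-connected 3D labelling with raster-deterministic labels, then
   per-cluster morphometry in physical units on the anisotropic voxel
   grid.

Two guard rails were added after characterizing the chain on synthetic
stacks. First, clusters below `min_keep` voxels or whose brightest
pre-squaring voxel is under `min_peak_snr` (default 10) robust noise SDs
above the background median are discarded: across the ~10^5 voxels of a
stack, noise extreme order statistics reach 6–7 robust SDs, while
condensates at ~10x enrichment sit far higher. Second, histogram
auto-thresholds presuppose that a foreground population exists; on a
condensate-free stack the Triangle method necessarily cuts into noise, so
object-free data should be segmented with an explicit absolute threshold
(`threshold =`), under which the result is empty.

**Two volumes per cluster.** `volume_um3` is voxel count times voxel
volume; it sums exactly to the segmented foreground volume (a conservation
property the tests assert), but for PSF-sized objects it includes the blur
halo down to the threshold level and overestimates accordingly.
`volume_flux_um3` divides the cluster's integrated pre-squaring intensity
by its plateau intensity (mean of the top 5% of cluster voxels); since
convolution with the PSF conserves flux, this readout is insensitive to
where the threshold cuts the halo. On synthetic stacks it recovers a
2 um droplet's volume within ~10%; droplets at or below the PSF scale are
still reported at their optically effective size — no estimator can undo
the resolution limit from a single image.

## Surface area and sphericity

Sphericity `psi = pi^(1/3) (6V)^(2/3) / A` needs a surface-area estimator
that is accurate for balls *and* for elongated shapes. Raw voxel-face
counting overestimates a digitized ball's area by ~1.5x (crushing psi to
~0.67); a midpoint marching-cubes mesh on binary data overestimates a ball
by ~9% and *underestimates* voxel-thin rods by ~30%; Crofton-style chord
counting is excellent on balls but undersamples structures thinner than
the diagonal line spacing. We therefore estimate area by normal-corrected
face projection: every exposed voxel face contributes its physical area
weighted by the cosine between the face normal and a local surface normal
taken from the gradient of a Gaussian-regularized indicator (regularization
scale 1.5x the smallest voxel dimension, evaluated at the face midpoint by
staggered differences). For a staircase digitization of a smooth surface
the weighted projections tile the true surface, so the estimator is
asymptotically unbiased for balls (measured: within ~2% at r = 10 voxels,
psi = 0.98) while remaining essentially exact for axis-aligned flat faces
(a 1 x 1 x 20 voxel rod gets psi = 0.47, close to the analytic box value
0.43). Because the regularization scales with the voxel size, psi is
exactly invariant under uniform scaling of the grid. Discretization can
push psi slightly above 1 for clusters near the 8-voxel reliability
floor; such clusters carry `reliable = FALSE`.

Sheets one voxel thick in exactly one dimension have no meaningful
enclosed volume and raise an error rather than returning a misleading
number.

## Cell typing and population summaries

A cell is typed by the equivalent diameter of its largest detected
droplet: type 1 below 1.0 um, type 2 from 1.0 to 3.6 um inclusive, type 3
above 3.6 um. The boundaries are configurable; both are assigned to type 2
(the interval is read as closed — the original rule leaves boundary
inclusivity unstated, and the closed convention makes the rule total and
monotone). The diameter estimator is the equivalent diameter
(area-derived in 2D, volume-derived in 3D); Feret or profile-width
definitions would differ for non-spherical clusters but the rule's
authors did not specify one. `presence_summary()` reports the fraction of
cluster-positive cells and the type distribution with the
`n = replicates/cells` annotation convention.

## Dynamic readouts

* **Formation latency**: time from stimulus onset to the first frame with
  at least `k = 3` clusters sustained for `m = 2` consecutive frames. The
  onset rule is ours — published latencies do not define their response
  call — so both parameters are explicit arguments; cells that never meet
  it are reported as non-responders (`NA`), mirroring injury experiments
  in which only a subset of cells responds.
* **Dispersion fraction**: `100 * (peak-window max - washout-window min) /
  peak-window max`. The washout *minimum* (not the endpoint) makes the
  estimate robust to re-nucleation blips. With 14% of droplets persistent,
  the generator implies a mean dispersion in the mid-80s percent range,
  which the pipeline recovers.
* **Integrated intensity**: background-subtracted *sum* (not mean) over
  the cell mask, because the conservation argument above applies to the
  integral; the mean is offered as an option.
* **Heatmap normalization**: each cell's count and intensity divided by
  that cell's own maximum, making cells of different expression levels
  comparable on one color scale. Display normalization
  (`display_normalize_per_frame`, frame mean to frame max) exists for
  visualization and Max-Entropy segmentation only and must never feed
  quantitative traces.

## The reference scene and what the validation shows

`demo_scene()` fixes the study conditions used by the test suite and the
acceptance script: one cell (radius 5 um, expression 80 AU/px) imaged at
0.2 um/px and 5 s per frame for 60 frames (5 minutes); stimulation spans
frames 11–44 with Ca2+ elevated 3x and kinase activity switching on 3
frames after stimulus onset; washout follows. Droplets nucleate at 5/min,
grow at 0.2 um/min from 0.6 um, dissolve at 6/min once activity stops,
14% are persistent, and nucleation keeps a 1.6 um minimum separation —
about five blob sigmas at nucleation size, the regime in which
prominence counting can resolve every droplet (the counting invariant is
conditional on separation; overlapping droplets coalesce in the model
rather than persisting as unresolvable pairs). Droplet amplitudes sit
roughly 9x above the shot-noise SD at elevated Ca2+.

Problem sizes were chosen so the whole suite runs on a laptop core: 64x64
pixel frames, 60-frame movies, 20 movies in the end-to-end recovery
experiment, 30-slice z-stacks, 1000-case oracle sweeps. On these scenes
the pipeline recovers per-frame droplet counts within +/-1 (in practice
exactly), onset latency within 2 frames, mean dispersion within a few
points of the generator truth, and integrated-trace/Ca2+ correlation
above 0.99. Those results validate the estimators under the generator's
assumptions; real acquisitions add drift, bleaching, and PSF structure
that this model deliberately omits.

## Numerical conventions

Axes are ordered (T or Z, Y, X); coordinates in files are 0-based, pixel
centres sit at half-integer micrometre positions; all physical quantities
are micrometres and seconds. Frame windows are inclusive frame-index
vectors. The 8-bit rescale rounds half-up. Threshold foregrounds are
strictly-greater comparisons. Tie-breaks are deterministic everywhere:
histogram peak ties resolve to the lowest bin, tied Kapur objectives to
the median tied level, equal-height maxima by raster order, and component
labels follow raster order of each component's first voxel. TIFF output
stores integer data up to 16 bits losslessly and other data as scaled
32-bit float, with calibration in a JSON sidecar. All randomness flows
from a single integer seed; the run manifest echoes the configuration,
package version and seed.
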