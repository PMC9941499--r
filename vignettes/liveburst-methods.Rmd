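---
title: "Quantifying transcriptional bursting and enhancer transcription with liveburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional bursting and enhancer transcription with liveburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liveburst)
```

# Scope

`liveburst` quantifies simultaneous gene (MS2) and non-coding enhancer (PP7)
transcription in live *Drosophila* embryos during nuclear cycle 14 (nc14).
It covers the full quantitative chain from multi-channel time-lapse stacks
to burst statistics:

1. **Segmentation** of nuclei from a histone-marker channel, per timeframe.
2. **Tracking** of nuclei into lineages by minimal centroid displacement.
3. **Trace extraction** of MS2/PP7 spot intensities with baseline zeroing.
4. **Burst calling** on smoothed traces, with burst frequency, size, total
   output, cumulative active fraction, and instantaneous/mean activities.
5. **Hub analysis**: radial enrichment of a transcription factor (e.g.
   Dorsal or Zelda) around transcription sites in single-timepoint 3D
   stacks, with random-site controls.
6. **Enhancer TSS genomics**: CAGE/RAMPAGE-style read counting on
   enhancers with exon-proximity filtering, TSS scores, and inward/outward
   orientation classification relative to TF-binding sites.

A synthetic-data generator provides movies, hub stacks and toy genomes with
known ground truth, so every stage is testable without the original imaging
data.

# The synthetic-data model

## Telegraph-model traces

The generator models each promoter as a two-state telegraph process at the
frame resolution of the movie: OFF switches ON with per-frame probability
`k_on`, ON switches OFF with probability `k_off`, and the initial state is
drawn from the stationary distribution `k_on / (k_on + k_off)`.  While ON,
the promoter loads `loading_rate` transcripts per frame; each transcript
contributes `intensity_per_transcript` signal units for `dwell_frames`
frames (a boxcar dwell).  The clean trace is the boxcar convolution of the
initiation sequence; the observed trace adds Gaussian noise and clips at
zero.  Ground-truth bursts are the maximal runs of positive clean signal.

Loading while ON is deliberately **deterministic** rather than Poisson:
with shot noise a momentarily ON promoter can emit nothing, so "promoter
ON" and "signal present" would decouple and ground-truth bursts would no
longer be a property of the switching process alone.  Burstiness in this
model comes from the telegraph switching; measurement scatter comes from
the additive Gaussian noise term (chosen over Poisson noise so window sums
in the extraction stage have a closed-form distribution).

Default kinetics (`k_on = 0.05`, `k_off = 0.2` per frame,
`loading_rate = 1.5`, `dwell_frames = 6`, `intensity_per_transcript = 100`,
180 frames) give mean ON episodes of 5 frames, a stationary ON fraction of
0.2, and a handful of bursts per nucleus per window — an nc14-like regime.
These values are documented defaults for the generator, not estimates of
embryo kinetics.

## Movies and hub stacks

`simulate_movie()` renders a nuclear-marker channel of blurred disks (hard
minimum spacing of 2.5 nucleus radii at placement) whose centroids jitter
frame-to-frame around their placed positions — nuclei wobble but never
interpenetrate, as in an nc14 interphase field — and MS2/PP7 channels in
which each nucleus carries an
isotropic 3D Gaussian spot (SD `psf_sd_px`) at its centre whose amplitude
follows an independent telegraph trace, on a constant background with
Gaussian voxel noise.  Random streams are split per nucleus, so enlarging a
cohort never perturbs existing nuclei.  The generator does **not** emulate
photobleaching, nuclear divisions, z-drift or realistic PSFs; tests passing
on this material validate the measurement chain, not robustness to those
effects.

`simulate_hub_stack()` renders single-timepoint two-channel 3D stacks: a TF
channel with a uniform nuclear level plus an optional isotropic Gaussian
"hub" centred on the transcription spot, and a spot channel marking the
spot.  In the packaged validation experiments the field outside the nucleus
is set to the nuclear level (the *nucleoplasm-interior regime*): real
nuclei are an order of magnitude larger than the 29-pixel analysis patch,
whereas the generator's nuclei are not, so without this choice patches at
off-centre random sites would straddle the nuclear boundary and the control
profiles could not be flat.

## Toy genomes

`simulate_genome_fixture()` writes BED-style tables on a synthetic
chromosome: each enhancer occupies its own 10-kb territory and receives
reads placed *by construction* either safely away from exons (counted) or
overlapping exon margins (filtered), plus intergenic background reads.
TF-binding sites sit inside enhancers, and stranded TSS peaks are placed so
that each enhancer realises a known orientation class (cycling through
inward, outward, both, none); "none" enhancers also carry an unstranded
decoy peak that classifiers must skip.

# The measurement chain

## Segmentation

Each timeframe's maximum z-projection of the nuclear channel is median
filtered, bandpassed, Otsu-binarised, and split into nuclei.  The bandpass
is realised as a difference of Gaussians with SDs derived from the pixel
size cuts as `cut / 2.355` (FWHM matching), defaults 5 and 25 px.  Touching
nuclei are split at markers — local maxima of the Euclidean distance
transform with a minimum separation of half the upper bandpass cut — and
each foreground pixel joins its nearest marker by geodesic-distance growth,
i.e. the Voronoi partition of the markers restricted to the mask.  The
partition is watertight (no background ridge between neighbours); a
1-pixel boundary discrepancy against tools that leave such ridges is
possible.  Near-constant frames yield an empty mask with a warning.  For TF
stacks, objects are filtered to an inclusive `[50, 200]` px area range
("between" read as inclusive) and the 2D mask is extended across z as a
prism — the simplest reading consistent with a single-projection
segmentation.  Masks are not manually corrected; the pipeline runs
unattended.

## Tracking

Nuclei in consecutive frames are matched greedily in ascending centroid
distance with one-to-one assignment (ties broken by label), which realises
the per-object minimum-displacement rule deterministically; there is no gap
closing.  A lineage is excluded wholesale when its region touches the image
border in any frame, or when a per-step displacement strictly exceeds the
nucleus length, defined here as the major-axis length of the region in the
earlier frame (the length itself is retained: strict inequality).

## Trace extraction

Per frame, the spot signal is the sum of the 5×5 window centred on the
brightest pixel of the nucleus region (row-major tie-break) minus the
region's median intensity times the window pixel count.  Window pixels
outside the region but inside the image are included; windows cropped by
the image border use the actual pixel count as the background multiplier.
The median is taken over all region pixels including the spot.  Each
trajectory is baseline-zeroed by subtracting its minimum, making traces
invariant to constant channel offsets.  Intensities stay in native camera
units; frame spacing is assumed uniform.

## Burst calling

Trajectories are smoothed by lowess (locally weighted linear regression,
tricube weights, span of 10 timeframes, no robustifying iterations — exact
on constant and linear signals).  A burst spans a maximal run of smoothed
values strictly above the threshold (the inclusive end convention keeps the
last supra-threshold frame).  Touching bursts are divided at any interior
frame whose smoothed value strictly decreased over the prior two frames and
strictly increases over the following two; the valley frame starts the
later fragment, and the rule re-applies left-to-right on the remainder.
Fragments shorter than five frames are discarded as false positives (the
filter also applies to fragments created by splitting).  Burst size
integrates the baseline-zeroed **raw** trace over the burst; total output
integrates it over all frames, so the sum of burst sizes never exceeds the
total output.

**Threshold.**  The method leaves the threshold open, and it depends on the
imaging calibration, so `burst_call_config()` requires it explicitly.  Two
documented choices are available: `default_burst_threshold()` places it `k`
MADs (default 3) of the sub-median fluctuations above the trace median —
a noise-floor estimate; the packaged recovery experiments instead fix it a
priori at half the extracted signal of one transcript-frame
(`0.5 * intensity_per_transcript * loading_rate * gaussian_window_mass(psf_sd)`),
the midpoint between the noise floor and the smallest real signal unit in
the generative model.

## Hub radial enrichment

Nuclei with the top fraction of integrated spot signal are pooled (ties at
the cutoff are all retained).  In each 3D-segmented nucleus, the brightest
spot voxel is located and the TF-channel patch (29×29 or 41×41 px) is
measured on that z-plane; patches that would leave the image are skipped
rather than padded, which would bias edge bins.  Random-site controls draw
the centre uniformly from the nucleus's segmented pixels on the same
z-plane.  Pixels are binned by integer-rounded distance from the centre;
each site's bin means are divided by its endmost *complete* bin — the last
bin inside the inscribed circle — so that bin's mean is exactly 1; corner
bins beyond the inscribed radius are reported but flagged incomplete.  The
SEM is computed across sites, matching error bars taken over a pooled site
set.  Condition comparisons use per-site curve areas (sum over complete
bins of enrichment − 1) under a two-sided rank-sum test.  No margin is
excluded around the true spot when drawing random sites; with a 3-px hub SD
the hub occupies a small fraction of the region, so the contamination is
negligible.

## Enhancer TSS genomics

All coordinates are 0-based half-open (BED).  Reads overlapping any exon
expanded by 50 bp on both sides are removed (≥ 1 bp overlap; a half-open
touch at the boundary is retention).  The TSS score is the filtered read
count per kb of enhancer ("reads per kb" is the documented unit choice).
The transcribed-enhancer threshold is an explicit analysis input; at a
threshold of exactly 0 the comparison is strict so zero-score enhancers are
never called transcribed.  Orientation: TF sites are assigned to enhancers
by overlap; stranded TSS peaks within ±500 bp of the site midpoint
(midpoints anchor both the window and the side; peaks are intervals and no
anchor is stated, so midpoints are the symmetric choice) are inward when
transcription proceeds toward the site — plus-strand on the left, or
minus-strand on the right, with peaks overlapping the site counted inward —
and outward otherwise.  Enhancers aggregate to `inward`, `outward`, `both`
(reported as its own class) or `none`.

# Statistics

Group comparisons use the two-sided Wilcoxon rank-sum test with Bonferroni
correction (`min(1, p × n_comparisons)`); exact p-values are used where
sample sizes permit and ties are absent, and a fully tied pooled sample is
reported as `p = 1`.

```{r stats-demo}
compare_groups(c(1, 2, 3), c(10, 11, 12), n_comparisons = 3)
```

# Validation experiments and their sizes

The test suite validates every stage against independent oracles; the
problem sizes below were chosen to make medians and rates stable while
keeping the suite quick to run.

* **Burst-caller equivalence** — 1,000 seeded telegraph traces of 180
  frames with kinetics drawn from broad ranges; burst intervals must be
  identical to an independently coded scan–split–filter reference.
* **Parameter recovery** — 20-nucleus, 180-frame movies, 3 seeds per ON
  rate over `k_on` in {0.02, 0.05, 0.1}/frame, full pipeline from pixels:
  recovered median burst frequency and size must increase with `k_on`,
  the frequency median must sit within 15% of ground truth, and tracking
  must produce zero identity swaps.
* **Hub recovery** — amplitude ratios {1, 1.25, 1.5, 2} at 50 sites each:
  central-bin enrichment within 10% of the closed-form value
  `(1 + a) / (1 + a e^{-R^2/2s^2})`; null and random-site profiles flat
  within 3×SEM (≥ 200 random sites); and the curve-area rank-sum test
  rejecting ratio 2 vs 1 at p < 0.01 in ≥ 95% of 100 repetitions.
* **Genomics equivalence** — filtering, scoring, windowing and
  classification identical to a quadratic brute-force oracle on 100 random
  annotations that include systematic ±2 bp boundary-offset reads.

```{r worked-example}
sim <- simulate_movie(movie_spec(n_nuclei = 6L,
                                 field_shape = c(60L, 2L, 128L, 128L),
                                 seed = 1),
                      telegraph_params(k_on = 0.05, k_off = 0.2))
masks <- lapply(1:60, function(t)
  segment_frame(max_project(sim$stack, "his2av", t)))
tracks <- apply_exclusions(link_frames(masks))
traces <- build_traces(sim$stack, masks, tracks, "ms2")
thr <- 0.5 * 100 * 1.5 * gaussian_window_mass(1.5)
bursts <- call_all_bursts(traces, burst_call_config(thr))
summarize_nuclei(bursts, traces)
```

# Numerical choices and degenerate inputs

* Argmax ties (spot pixel, brightest voxel) break in row-major / ascending
  coordinate order, making extraction deterministic.
* Traces shorter than the smoothing window are smoothed with the span
  clamped to the whole trace, with a warning.
* Empty frames terminate all active lineages; empty masks are legal.
* `select_top_sites` retains all nuclei tied at the quantile cutoff, so the
  retained count can exceed the nominal fraction.
* Distance binning uses round-half-up of the Euclidean pixel distance.
* All generators are bit-reproducible given their seed, and pipeline runs
  with identical configuration produce byte-identical CSV outputs.

# Known limitations

* The 3D nucleus region is a z-prism of the 2D mask, not a per-slice
  segmentation.
* No sub-pixel spot localisation, 3D spot fitting, chromatic registration,
  photobleaching correction or division tracking.
* The burst caller is threshold-based by design; no hidden-Markov or
  Bayesian inference of promoter states.
* Whether lineages should be truncated at an offending frame rather than
  excluded wholesale is an open reading; exclusion of the whole lineage is
  implemented.
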