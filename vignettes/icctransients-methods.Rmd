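---
title: "Quantifying Ca2+ transients in ICC-DMP: models and methods"
author: "icctransients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Ca2+ transients in ICC-DMP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icctransients)
```

## The biological measurement problem

Interstitial cells of Cajal of the intestinal deep muscular plexus
(ICC-DMP) are spindle-shaped cells, tens of micrometres long, that fire
ongoing, localized, stochastic Ca2+ transients from a handful of fixed
subcellular firing sites. Each transient is a brief wave: it initiates at a
site, propagates some micrometres along the cell axis, and decays within a
few hundred milliseconds. Enteric inhibitory neurotransmission (probed by
electrical field stimulation, EFS) silences this activity; individual sites
then *escape* from inhibition at heterogeneous times during the train.

The package quantifies such recordings through the field's standard
reduction: a whole-cell ROI collapses the movie onto the cell's centerline
to give a spatio-temporal (ST) map -- position along the cell versus time,
in baseline-normalized fluorescence (dF/F0) -- on which events are
detected, measured, clustered into firing sites, and epoch-analysed around
the stimulation window. Because raw recordings of this preparation are not
publicly deposited, the package pairs the analysis chain with a calibrated
synthetic-recording generator carrying a ground-truth ledger, so every
stage is validated by parameter recovery.

## The synthetic recording model

`GeneratorConfig()` + `simulateRecording()` emulate a confocal recording
at 33 frames/s and 0.5 um/pixel of a single spindle cell (default 80 x 6
um, elliptical width profile, baseline 1000 counts inside the cell over a
dim background). The pieces:

* **Firing sites.** The per-cell site count is drawn from a Poisson
  distribution with mean 5.2 clamped to [1, 13] (a stand-in: the real
  count distribution is unknown beyond its mean and range). Sites sit
  uniformly along the centerline with a minimum separation of twice the
  site-clustering linkage (10 um) and a 2 um tip margin, so ground-truth
  sites are resolvable by construction. On an 80 um centerline at most 8
  sites can be packed at that separation; rarer larger draws are reduced
  to 8 with a warning.
* **Event trains.** Each site fires as a homogeneous Poisson process at
  `cellRate / nSites` -- the minimal model for activity that is ongoing,
  stochastic and uncoordinated, and one that keeps recovery targets
  analytic. The baseline parameterization is 1.05 events/s per cell.
* **Event kinetics.** Per-event amplitude (mean 0.8 dF/F0), FDHM (189
  ms), spatial spread (11.1 um) and velocity (71.4 um/s) are lognormal
  around the configured means with CV 0.3 (`ampCv`, `kineticCv`);
  reported condition tables give only means of means, so the CV is a
  modelling choice producing realistic dispersion without sign
  violations. Propagation direction is +/-1 with equal probability.
* **The rendered kernel.** An event is a travelling wave: temporally, a
  linear rise over 30 ms (one frame; rise kinetics are not documented for
  this indicator/preparation, so one frame is the minimal choice)
  followed by an exponential decay whose time constant is set so the
  half-maximum width of the trace equals the event's FDHM
  (tau = (FDHM - rise/2) / ln 2). Spatially, a fully activated plateau
  flanked by Gaussian edges (sigma 1 um) whose leading edge advances
  from the initiation locus at the event's velocity until the total
  half-maximum extent equals the spread; each position experiences the
  temporal kernel delayed by its distance over the velocity. Events
  reaching past the cell tips are truncated at the mask edge (counted,
  not an error). Pixels get Gaussian noise (SD `noiseSd * baselineF0`,
  default 0.05), optional rigid integer drift, clipping at zero and
  16-bit quantization.
* **EFS and escape.** With an `EFSProtocol()` (default: 5 s train at 10
  Hz starting at 7.5 s of a 20 s recording, so the 5 s pre window, the
  longest possible escape and a 5 s post window all fit), every site
  draws an escape latency from a truncated normal, mean 3.8 s, SD 1.8 s,
  truncated to [0.2, 9.9] s. The site is silent from EFS onset until its
  latency elapses; its first post-onset event occurs exactly at
  onset + latency -- that event *is* the observable escape -- after which
  it fires at `postEscapeGain` (default 1.5) times its basal rate for the
  rest of the recording (the post-train enhancement is qualitative in the
  source material; the gain is configurable and not a recovery target).

### Intra-cell latency correlation

Site latencies within a cell share a Gaussian-copula correlation
(`escapeRho`, default 0.325); cells are mutually independent. Fully
independent site draws are inconsistent with the two summary statistics
the latency model is built to reproduce: with a TN(3.8, 1.8, [0.2, 9.9])
marginal and ~5.2 sites per cell, the expected *minimum* (first site to
escape) would be about 2.08 s, whereas the first-site mean to be matched
is 2.4 s. A modest positive correlation raises the expected minimum
without touching the pooled marginal; 0.325 was obtained once by solving
E[min] = 2.4 numerically under the default site-count rule. Biologically
this says sites within one cell see partially shared inhibitory drive,
while cells escape independently of each other -- consistent with the
reported asynchrony between cells.

### What the generator does not emulate

No photophysics (bleaching, indicator binding kinetics), no 3-D optics or
PSF, no non-rigid deformation (recordings of this preparation are made
under nicardipine, so only rigid drift is modelled), no inter-cell
coordination, and no sub-threshold "residual" events during the inhibited
phase. Passing recovery tests therefore demonstrates that the *pipeline*
is unbiased under the stated model, not that the model captures every
feature of real movies.

## The analysis chain

### Stabilization

`stabilizeMovie()` registers each frame to a reference (first pre-EFS
frame) by integer-pixel rigid translation maximizing the FFT
cross-correlation, filling exposed borders with the frame median. Shifts
beyond 20% of a frame dimension flag the frame unstable rather than
applying an implausible correction. Sub-pixel or non-rigid registration is
deliberately out of scope.

### ST map and baseline

`buildSTMap()` assigns every in-polygon pixel to its nearest centerline
point and averages transversely (the mean, not the max, keeps amplitudes
comparable across cell widths), then normalizes each bin to
dF/F0 = (F - F0)/F0 with F0 the 10th percentile of the bin's trace
(over the pre-EFS window when a protocol is known). A percentile resists
contamination by frequent transients; the documented floor of 1 count
keeps the ratio defined on degenerate bins. Conventions: bins and frames
are 0-based in all reported quantities; time is frame/frameRate seconds;
position is bin x binSize micrometres; all intervals are half-open
[start, end).

A percentile baseline sits slightly *below* the mean of a noisy quiescent
trace, so quiescent dF/F0 is biased a little above zero. Detection and
measurement therefore centre each bin's trace at its median first;
without this the effective detection threshold would silently drop and
amplitudes would inflate.

### Event detection

`detectEvents()` estimates the noise SD robustly -- the SD of a bin's
dF/F0 after excluding its top 25% of values, divided by 0.73123, the
analytic SD of a unit normal truncated at its 75th percentile (the same
kind of consistency factor as the MAD's 1.4826). The estimate is per bin
because the transverse collapse averages a different number of pixels in
every bin of a spindle-shaped cell: mid-cell bins average ~12 pixels, tip
bins 1-3, so map noise is strongly heteroscedastic and a single per-map
SD either floods the tips with false positives or desensitizes the body.

Cells above `thresholdK * sigma` (default 3) form 8-connected components;
a component must span at least 2 frames and 2 bins and contain at least
one cell reaching `minPeakK * sigma` (default twice the base threshold --
the usual dual-threshold arrangement; without it, the decaying tails of
real events shed small threshold-flicker fragments that masquerade as
events). Components are then split recursively into single events:

* at temporal saddles dipping below half of both flanking peaks (rapid
  successive events at one site);
* at the analogous spatial saddles (concurrent events at neighbouring
  sites whose footprints touch);
* at arrival-time watersheds: a merged double wave shows two local minima
  of the per-bin half-max arrival time separated by a late-arrival
  collision ridge; a cut requires origins at least 10 bins apart and a
  ridge at least 2 frames proud, which near-simultaneous escape events at
  neighbouring sites produce and single waves do not.

Event count is exactly non-increasing in the threshold on noise-free
maps; under noise, a sub-half saddle crossing the sweep can occasionally
nudge a count up by one -- an inherent property of threshold/connectivity
detection, not an implementation artifact.

### Per-event metrics

`measureEvents()` works on the median-centred map. Amplitude is the
footprint maximum; the peak cell takes the earliest frame, then the
lowest bin, on exact ties, so results are platform-independent. FDHM is
the contiguous time around the peak for which the peak-bin trace stays at
or above half amplitude, both crossings linearly interpolated between
frames (exact for the linear rise; the interpolation error on the
exponential decay is well under a frame). Spatial spread is the total
half-max extent of the footprint, `(max bin - min bin + 1) * binSize`;
the initiation-to-farthest-half-max distance is reported alongside as
`travel_um` because "distance propagated" admits both readings.

The initiation locus is the bin whose trace first reaches half maximum
within the footprint -- the origin of a travelling wave rises first. When
several bins first clear half on the same frame (a whole plateau section
can), their sub-frame crossing times, interpolated from the previous
frame, break the tie; this keeps the locus within one bin on noise-free
renders in either propagation direction and is robust to single-cell
noise at the detection fringe, where a raw earliest-frame rule is not.

Velocity is the magnitude of the least-squares slope of the leading-edge
position (the farthest half-max bin on the event's propagation side,
signed) against time, from initiation to peak, restricted to the edge's
advance phase -- once the front stalls, further frames only dilute the
slope. Events spanning fewer than 3 frames report 0; events with fewer
than two usable edge frames report `NA`, and window summaries average
over events with a defined estimate. At 33 fps and 0.5 um bins a
two-point slope carries an irreducible quantization scale of roughly
`binSize * frameRate` (~16 um/s), so per-event velocities are coarse;
cohort means are the meaningful quantity.

### Sites, windows, escape

`clusterSites()` is single-linkage agglomerative clustering of initiation
loci cut at 5 um -- in one dimension exactly the sorted-gap rule, which is
what is implemented (and cross-checked against `hclust` in the tests).
The assignment partitions the events; linkage to infinity gives one site,
linkage to 0+ one site per distinct locus.

`windowMetrics()` assigns events to protocol windows by initiation time
over half-open intervals (an event exactly at EFS onset belongs to the
train, not the pre window). Defaults mirror the 5 s train: pre = 5 s
before onset, the first 2 s of the train (the inhibitory phase), the
train remainder, and 5 s post-train; edges are configurable and windows
reaching past the recording are truncated with the duration adjusted.
Empty windows report frequency 0 and absent (NA) means -- never
zero-valued means.

`escapeLatencies()` reports, per site, the initiation time of the site's
first event at or after onset minus onset (0 for an event exactly at
onset); sites with no such event are censored explicitly and excluded
from summaries, and the first-site latency is the minimum uncensored
value. Initiation (not peak) is used because the escape is the first
appearance of a transient.

### Summary statistics

`summarizeGroup()` implements the mean +/- SEM convention with animal
(`n`) and cell (`c`) counts carried alongside; per-cell values are the
statistical unit, with animal ids kept so a per-animal re-aggregation is
one step away. `compareGroups()` screens each group with the
D'Agostino-Pearson omnibus K2 test (implemented from the standard skew
and kurtosis transforms and verified against an independent reference
implementation; skipped with a flag below 8 observations), then runs the
two-sided Student's t-test (paired or unpaired) or one-way ANOVA for more
than two groups. The parametric test is reported even when the screen
fails -- the package mirrors the field's practice and raises a
`non_normal` flag instead. A paired contrast with all-zero differences is
reported as p = 1 with a `zero_variance` flag rather than NaN. No
multiple-testing correction is applied. `starCode()` maps p values to the
conventional strict-inequality star coding.

## Validation strategy and problem sizes

The test suite validates each operator against independent oracles:
brute-force flood fill for component labelling, closed-form crossings for
FDHM, exhaustive shift search for registration, brute-force pairwise
merging and `hclust` for clustering, closed-form Poisson and numerically
integrated truncated-normal moments for the generator, and a simulated
null for the type-I error of the comparison machinery.

Cohort-level validation simulates 48 stimulated cells (20 s at 33 fps,
the c = 48 convention of the condition tables) and 100 unstimulated cells
for site-count recovery, runs the complete pipeline on every rendered
movie, and compares cohort estimates with the generator's ground truth;
`runRecover()` exposes the same machinery to users. These sizes keep a
full run in a few minutes on one core while leaving Monte-Carlo error
well below the tolerances being checked.

## Known limitations

* **Merged events.** At 33 fps, two events closer than ~0.2 s at the same
  site, or simultaneous events at neighbouring sites whose plateaus
  overlap, are genuinely one supra-threshold blob. The saddle and
  watershed rules recover most, but a few percent of events stay merged;
  cohort frequency reads a few percent low, and a site whose escape event
  is swallowed by a neighbour's reports its *next* event instead, so the
  pooled escape-latency mean reads a few percent high.
* **Early-window activity under the symmetric latency model.** The
  truncated normal places ~14% of site latencies below 2 s, so the
  simulated first-2-s window retains substantially more residual activity
  (frequency and active sites) than real recordings show; empirical
  escape-time histograms are right-skewed. This is a property of the
  latency stand-in, carried deliberately for its analytic transparency,
  and it does not affect the pre-window, site-count or latency-mean
  recoveries.
* **Amplitude under noise.** The amplitude of an event is a maximum over
  a noisy footprint and reads high by a few percent at the default noise
  level; the median-centring removes the larger baseline-offset term but
  not the order-statistic term.
* **Velocity granularity.** Per-event velocities are quantized by the
  bin/frame grid (see above); only cohort means should be interpreted.

## A worked example

```{r example, eval = FALSE}
cfg <- presetConfig("baseline_efs", seed = 7)
sim <- simulateRecording(cfg)
res <- analyzeRecording(sim$movie, sim$roi, protocol = cfg@efs)
res$windows[, c("label", "frequency_hz", "mean_amplitude_dff")]
res$escape$perSite
plotSTMap(res$stmap)
```

`runRecover("baseline_efs", nCells = 48, seed = 1)` reproduces the full
cohort recovery table, and `scripts/acceptance.R` (repository root) writes
the same quantities as JSON.
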