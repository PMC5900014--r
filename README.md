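# icctransients

Quantification of localized Ca2+ transients in interstitial cells of Cajal
of the intestinal deep muscular plexus (ICC-DMP), for researchers studying
enteric neural regulation of gastrointestinal motility with
genetically-encoded Ca2+ indicators.

ICC-DMP fire ongoing, stochastic Ca2+ transients from a handful of fixed
firing sites per cell. Enteric inhibitory input (electrical field
stimulation, EFS) silences the activity transiently, and each site then
*escapes* from inhibition after its own latency. The package implements the
standard quantification chain for such recordings and a calibrated
synthetic-recording generator for validating it:

* **ST maps** — a movie plus a whole-cell ROI becomes a spatio-temporal
  map: mean fluorescence along the cell's centerline versus time,
  normalized to ΔF/F₀ = (F − F₀)/F₀ with F₀ the 10th percentile of each
  position's trace (pre-stimulus window when a protocol is known), after
  rigid integer-pixel stabilization.
* **Events** — transients are segmented as 8-connected supra-threshold
  components (per-bin robust noise SD, 3σ threshold with a 6σ peak
  criterion; saddle and arrival-time splitting of merged events) and
  measured: peak amplitude (ΔF/F₀), full duration at half maximum (FDHM,
  ms; interpolated half crossings), spatial spread (total half-max extent,
  µm), and propagation velocity (leading-edge regression, µm/s).
* **Firing sites** — initiation loci are clustered by single linkage at
  5 µm; per-window summaries (event frequency in s⁻¹, means of the event
  metrics, active sites) and per-site escape latencies (first event at or
  after EFS onset) reproduce the field's condition tables.
* **Statistics** — mean ± SEM with the n (animals) / c (cells) convention,
  D'Agostino–Pearson normality screening, Student's t-test / one-way
  ANOVA, star-coded p values.
* **Synthetic recordings** — `simulateRecording()` renders 16-bit movies
  of spindle cells (33 fps, 0.5 µm/px) with site-localized travelling-wave
  events, Poisson trains, truncated-normal escape latencies and photon
  noise, together with the ground-truth ledger, so the whole pipeline is
  testable by parameter recovery. `presetConfig()` carries the
  baseline/EFS parameterization and the pharmacological condition presets.

## Worked example

Simulate one stimulated cell and analyse it end to end:

```r
library(icctransients)

cfg <- presetConfig("baseline_efs", seed = 7)   # 20 s, EFS at 7.5 s for 5 s
sim <- simulateRecording(cfg)
res <- analyzeRecording(sim$movie, sim$roi, protocol = cfg@efs)

res$windows[, c("label", "duration_s", "n_events", "frequency_hz",
                "mean_amplitude_dff", "mean_fdhm_ms", "active_sites")]
#>         label duration_s n_events frequency_hz mean_amplitude_dff mean_fdhm_ms active_sites
#> 1         pre          5        4         0.80              0.891          302            3
#> 2 efs_first2s          2        3         1.50              0.736          212            3
#> 3    efs_late          3        4         1.33              0.871          158            3
#> 4        post          5        8         1.60              0.870          189            6

res$escape$perSite
#>   site_id latency_s censored
#> 1       1     2.712    FALSE
#> 2       2     1.864    FALSE
#> 3       3     0.742    FALSE
#> 4       4     3.076    FALSE
#> 5       5     2.985    FALSE
#> 6       6     5.682    FALSE
#> 7       7     1.682    FALSE
```

The window table gives the per-epoch event frequency (events per second
per cell) and metric means; `escape$perSite` is the per-site inhibitory
period — the time from EFS onset to the site's first transient. This cell
drew 8 ground-truth sites whose latencies were 2.70, 1.93, 1.84, 0.74,
3.06, 2.98, 5.67 and 1.66 s; the pipeline recovers 7 sites (two close
sites merge) with latencies matching to a few hundredths of a second.
`plotSTMap(res$stmap)` displays the underlying kymograph.

Cohort-level recovery — simulate many cells, run the full pipeline and
compare against the generator's ground truth:

```r
rec <- runRecover("baseline_efs", nCells = 48, seed = 1)
rec$report
```

File-level entry points (`runSimulate()`, `runAnalyze()`) read and write
multi-frame 16-bit TIFF movies with JSON sidecars, ROI JSON
(polygon + centerline, 0-based pixel coordinates) and CSV tables; a thin
command-line wrapper is installed at
`system.file("scripts/icctransients-cli.R", package = "icctransients")`.

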