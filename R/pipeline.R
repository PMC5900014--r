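#' @include AllClasses.R
NULL

#' End-to-end analysis of one recording
#'
#' Runs the full quantification chain on one movie + ROI: rigid
#' stabilization ([stabilizeMovie()]), ST-map construction with
#' \eqn{\Delta F/F_0} normalization ([buildSTMap()]; with a protocol the
#' baseline window is the pre-EFS epoch), event detection
#' ([detectEvents()]), per-event metrics ([measureEvents()]), firing-site
#' clustering ([clusterSites()]) and, when an [EFSProtocol()] is supplied,
#' window summaries ([windowMetrics()]) and escape latencies
#' ([escapeLatencies()]).
#'
#' @param movie a [CalciumMovie()].
#' @param roi a [CellROI()].
#' @param protocol an [EFSProtocol()] or `NULL`.
#' @param thresholdK,minFrames,minBins detection parameters, see
#'   [detectEvents()].
#' @param linkageUm site-clustering linkage distance, see [clusterSites()].
#' @param stabilize run rigid registration first (default `TRUE`).
#' @return A list: `stmap`, `events`, `sites`, `windows` (or `NULL`),
#'   `escape` (or `NULL`), `shifts` (or `NULL`), `sigma`, `log`.
#' @examples
#' sim <- simulateRecording(presetConfig("baseline", duration = 5, seed = 2))
#' res <- analyzeRecording(sim$movie, sim$roi)
#' nrow(res$events)
#' @export
analyzeRecording <- function(movie, roi, protocol = NULL, thresholdK = 3,
                             minFrames = 2L, minBins = 2L, linkageUm = 5,
                             stabilize = TRUE) {
  log <- logLine(character(), sprintf(
    "analyzeRecording: %d frames, thresholdK=%g, linkageUm=%g",
    nFrames(movie), thresholdK, linkageUm))
  shifts <- NULL
  if (stabilize) {
    st <- stabilizeMovie(movie)
    movie <- st$movie
    shifts <- st$shifts
    if (any(shifts$unstable))
      log <- logLine(log, sprintf("%d unstable frame(s) flagged",
                                  sum(shifts$unstable)))
  }
  f0Frames <- NULL
  if (!is.null(protocol)) {
    nPre <- floor(protocol@onset * movie@frameRate)
    if (nPre >= 33) f0Frames <- seq_len(nPre)
  }
  stmap <- buildSTMap(movie, roi, f0Frames = f0Frames)
  det <- detectEvents(stmap, thresholdK = thresholdK,
                      minFrames = minFrames, minBins = minBins)
  events <- measureEvents(det, stmap)
  cs <- clusterSites(events, linkageUm = linkageUm)
  log <- logLine(log, sprintf("%d event(s) in %d site(s), sigma=%.4g",
                              nrow(events), nrow(cs$sites), det$sigma))
  windows <- NULL
  escape <- NULL
  if (!is.null(protocol)) {
    dur <- nFrames(movie) / movie@frameRate
    windows <- windowMetrics(cs$events, cs$sites, protocol,
                             recordingEnd = dur)
    escape <- escapeLatencies(cs$events, cs$sites, protocol)
  }
  list(stmap = stmap, events = cs$events, sites = cs$sites,
       windows = windows, escape = escape, shifts = shifts,
       sigma = det$sigma, log = log)
}

#' Simulate a cohort of recordings to disk
#'
#' Simulates `nCells` recordings from a preset (or explicit config) and
#' writes, per cell, the movie TIFF with JSON sidecar, the ROI JSON and the
#' ground-truth CSVs. Deterministic under `seed` (cell `i` uses
#' `seed + i`).
#'
#' @param preset preset name for [presetConfig()], or a [GeneratorConfig()].
#' @param nCells number of cells to simulate.
#' @param seed integer base seed.
#' @param outDir output directory (created if needed).
#' @param ... overrides forwarded to [presetConfig()].
#' @return invisibly, a data.frame of written file paths.
#' @export
runSimulate <- function(preset = "baseline", nCells = 1L, seed = 1L,
                        outDir, ...) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", outDir, "'")
  files <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    cfg <- if (is(preset, "GeneratorConfig")) preset else
      presetConfig(preset, seed = seed + i, ...)
    sim <- simulateRecording(cfg, seed = seed + i)
    prefix <- sprintf("cell%03d", i)
    mp <- file.path(outDir, paste0(prefix, ".tif"))
    writeMovie(sim$movie, mp, efs = cfg@efs)
    rp <- file.path(outDir, paste0(prefix, "_roi.json"))
    writeROI(sim$roi, rp)
    writeGroundTruth(sim$truth, outDir, prefix)
    files[[i]] <- data.frame(cell = i, movie = mp, roi = rp)
  }
  invisible(do.call(rbind, files))
}

#' Analyze a recording from files
#'
#' File-level entry point: reads a movie TIFF (+ JSON sidecar) and an ROI
#' JSON, runs [analyzeRecording()] and writes `events.csv`, `sites.csv`,
#' and (with a protocol) `windows.csv` and `escape.csv`, plus a run log
#' (`analyze_log.txt`, line-oriented with ISO timestamps, recording the
#' parameters and seed-independent provenance).
#'
#' @param moviePath path to the movie TIFF.
#' @param roiPath path to the ROI JSON.
#' @param outDir output directory (created if needed).
#' @param efsOnset,efsDuration EFS protocol (seconds); defaults taken from
#'   the movie sidecar when present, `NULL` for unstimulated recordings.
#' @param thresholdK,linkageUm analysis parameters.
#' @return invisibly, the [analyzeRecording()] result.
#' @export
runAnalyze <- function(moviePath, roiPath, outDir, efsOnset = NULL,
                       efsDuration = NULL, thresholdK = 3, linkageUm = 5) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", outDir, "'")
  movie <- readMovie(moviePath)
  roi <- readROI(roiPath)
  sidecar <- paste0(moviePath, ".json")
  if (is.null(efsOnset) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    efsOnset <- meta$efs_onset
    efsDuration <- meta$efs_duration
  }
  protocol <- if (!is.null(efsOnset))
    EFSProtocol(onset = efsOnset,
                trainDuration = if (is.null(efsDuration)) 5 else efsDuration)
  else NULL
  res <- analyzeRecording(movie, roi, protocol = protocol,
                          thresholdK = thresholdK, linkageUm = linkageUm)
  utils::write.csv(res$events, file.path(outDir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(res$sites, file.path(outDir, "sites.csv"),
                   row.names = FALSE)
  if (!is.null(res$windows))
    utils::write.csv(res$windows, file.path(outDir, "windows.csv"),
                     row.names = FALSE)
  if (!is.null(res$escape))
    utils::write.csv(res$escape$perSite, file.path(outDir, "escape.csv"),
                     row.names = FALSE)
  log <- c(res$log, logLine(character(), sprintf(
    "inputs: %s + %s; package icctransients %s", moviePath, roiPath,
    as.character(utils::packageVersion("icctransients")))))
  writeLines(log, file.path(outDir, "analyze_log.txt"))
  invisible(res)
}

## One simulated cell run through the full pipeline; returns per-cell
## pipeline estimates next to the ground-truth values of the same cell.
.recoverOneCell <- function(cfg, seed) {
  sim <- simulateRecording(cfg, seed = seed)
  res <- analyzeRecording(sim$movie, sim$roi, protocol = cfg@efs)
  truth <- sim$truth
  tev <- truth@events

  est <- list(nSites = nrow(res$sites))
  tru <- list(nSites = nrow(truth@sites))

  if (!is.null(cfg@efs)) {
    w <- res$windows
    pre <- w[w$label == "pre", ]
    e2 <- w[w$label == "efs_first2s", ]
    est <- c(est, list(
      freqPre = pre$frequency_hz, ampPre = pre$mean_amplitude_dff,
      fdhmPre = pre$mean_fdhm_ms, spreadPre = pre$mean_spread_um,
      velPre = pre$mean_velocity_um_s, freq2s = e2$frequency_hz,
      active2s = e2$active_sites,
      firstLat = res$escape$firstSiteLatency,
      lats = list(res$escape$perSite$latency_s[!res$escape$perSite$censored])))
    onset <- cfg@efs@onset
    inPre <- tev$t_init_s >= onset - 5 & tev$t_init_s < onset
    in2s <- tev$t_init_s >= onset & tev$t_init_s < onset + 2
    tru <- c(tru, list(
      freqPre = sum(inPre) / 5,
      ampPre = if (any(inPre)) mean(tev$amplitude_dff[inPre]) else NA,
      fdhmPre = if (any(inPre)) mean(tev$fdhm_ms[inPre]) else NA,
      spreadPre = if (any(inPre)) mean(tev$spread_um[inPre]) else NA,
      velPre = if (any(inPre)) mean(tev$velocity_um_s[inPre]) else NA,
      freq2s = sum(in2s) / 2,
      active2s = length(unique(tev$site_id[in2s])),
      firstLat = min(truth@escape$latency_s),
      lats = list(truth@escape$latency_s)))
  } else {
    dur <- cfg@duration
    est$freq <- nrow(res$events) / dur
    tru$freq <- nrow(tev) / dur
  }
  list(est = est, tru = tru)
}

#' Cohort-level parameter recovery
#'
#' Simulates a cohort of cells from a preset, runs the full analysis
#' pipeline on every rendered movie, and compares the pipeline's cohort
#' estimates against the generator's ground truth for the same cells:
#' pre-EFS frequency/amplitude/FDHM/spread/velocity, first-2-s EFS
#' frequency and active sites, sites per cell, and first-site and pooled
#' per-site escape latencies (EFS presets), or overall frequency and sites
#' per cell (unstimulated presets). Each row reports the estimate, the
#' ground-truth value, the estimate's 3 SE interval and whether the truth
#' falls inside it.
#'
#' @param preset preset name ([presetConfig()]) or a [GeneratorConfig()].
#' @param nCells cohort size.
#' @param seed base seed (cell `i` uses `seed + i`).
#' @param duration recording length in seconds.
#' @param outDir optional directory to write `recovery.csv` to.
#' @return A list: `report` (data.frame `metric`, `estimate`, `truth`,
#'   `se`, `lo`, `hi`, `within`, `n`), `perCell` (list of per-cell
#'   estimate/truth pairs).
#' @examples
#' \donttest{
#' rec <- runRecover("baseline_efs", nCells = 4, seed = 1)
#' rec$report
#' }
#' @export
runRecover <- function(preset = "baseline_efs", nCells = 48L, seed = 1L,
                       duration = 20, outDir = NULL) {
  cells <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    cfg <- if (is(preset, "GeneratorConfig")) preset else
      presetConfig(preset, duration = duration, seed = seed + i)
    cells[[i]] <- .recoverOneCell(cfg, seed = seed + i)
  }
  scalarMetrics <- setdiff(names(cells[[1]]$est), "lats")
  rows <- lapply(scalarMetrics, function(m) {
    est <- vapply(cells, function(x) as.numeric(x$est[[m]]), numeric(1))
    tru <- vapply(cells, function(x) as.numeric(x$tru[[m]]), numeric(1))
    ok <- is.finite(est)
    se <- stats::sd(est[ok]) / sqrt(sum(ok))
    data.frame(metric = m, estimate = mean(est[ok]),
               truth = mean(tru[is.finite(tru)]), se = se, n = sum(ok))
  })
  if ("lats" %in% names(cells[[1]]$est)) {
    el <- unlist(lapply(cells, function(x) x$est$lats))
    tl <- unlist(lapply(cells, function(x) x$tru$lats))
    rows <- c(rows, list(data.frame(
      metric = "latPooled", estimate = mean(el), truth = mean(tl),
      se = stats::sd(el) / sqrt(length(el)), n = length(el))))
  }
  report <- do.call(rbind, rows)
  report$lo <- report$estimate - 3 * report$se
  report$hi <- report$estimate + 3 * report$se
  report$within <- report$truth >= report$lo & report$truth <= report$hi
  if (!is.null(outDir)) {
    if (!dir.exists(outDir))
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(outDir, "recovery.csv"),
                     row.names = FALSE)
  }
  list(report = report, perCell = cells)
}
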