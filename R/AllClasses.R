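#' @include AllGenerics.R
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## EFSProtocol
## ---------------------------------------------------------------------------

#' Electrical field stimulation protocol
#'
#' Describes an EFS epoch within a recording: when the train starts, how long
#' it lasts, and the statistical model of per-site escape from inhibition.
#' During EFS, Ca2+ firing sites are silenced; each site then escapes after a
#' latency drawn from a truncated normal distribution
#' (`escapeMean`, `escapeSd`, truncated to `[escapeMin, escapeMax]`).
#' Latencies of sites within one cell share a Gaussian-copula correlation
#' `escapeRho` (cells are mutually independent), and once a site has escaped
#' its firing rate is multiplied by `postEscapeGain` for the remainder of the
#' recording.
#'
#' @param onset EFS train onset, seconds from recording start.
#' @param trainDuration train duration in seconds (must be > 0).
#' @param pulseFreq pulse frequency in Hz (metadata only; the pulses
#'   themselves are not modelled).
#' @param escapeMean,escapeSd mean and SD (s) of the latent normal used for
#'   per-site escape latencies.
#' @param escapeMin,escapeMax truncation bounds (s) of the latency
#'   distribution; `escapeMin <= escapeMean <= escapeMax` and
#'   `escapeMin >= 0`.
#' @param escapeRho intra-cell Gaussian-copula correlation of site latencies
#'   in `[0, 1)`. The default 0.325 makes the expected first-site (minimum)
#'   latency equal 2.4 s under the default site-count rule while leaving the
#'   marginal latency distribution untouched.
#' @param postEscapeGain dimensionless multiplier applied to a site's firing
#'   rate after it escapes inhibition.
#' @return An `EFSProtocol` object.
#' @seealso [GeneratorConfig()], [escapeLatencies()]
#' @examples
#' EFSProtocol(onset = 7.5, trainDuration = 5)
#' @export
EFSProtocol <- function(onset = 7.5, trainDuration = 5, pulseFreq = 10,
                        escapeMean = 3.8, escapeSd = 1.8,
                        escapeMin = 0.2, escapeMax = 9.9,
                        escapeRho = 0.325, postEscapeGain = 1.5) {
  new("EFSProtocol", onset = onset, trainDuration = trainDuration,
      pulseFreq = pulseFreq, escapeMean = escapeMean, escapeSd = escapeSd,
      escapeMin = escapeMin, escapeMax = escapeMax, escapeRho = escapeRho,
      postEscapeGain = postEscapeGain)
}

#' @rdname EFSProtocol
#' @export
setClass("EFSProtocol",
  representation(onset = "numeric", trainDuration = "numeric",
                 pulseFreq = "numeric", escapeMean = "numeric",
                 escapeSd = "numeric", escapeMin = "numeric",
                 escapeMax = "numeric", escapeRho = "numeric",
                 postEscapeGain = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@onset) != 1L || object@onset < 0)
      msg <- c(msg, "'onset' must be a single non-negative number")
    if (object@trainDuration <= 0)
      msg <- c(msg, "'trainDuration' must be > 0")
    if (object@escapeMin < 0)
      msg <- c(msg, "'escapeMin' must be >= 0")
    if (object@escapeMin > object@escapeMean ||
        object@escapeMean > object@escapeMax)
      msg <- c(msg, "need escapeMin <= escapeMean <= escapeMax")
    if (object@escapeSd <= 0)
      msg <- c(msg, "'escapeSd' must be > 0")
    if (object@escapeRho < 0 || object@escapeRho >= 1)
      msg <- c(msg, "'escapeRho' must be in [0, 1)")
    if (object@postEscapeGain < 0)
      msg <- c(msg, "'postEscapeGain' must be >= 0")
    if (length(msg)) msg else TRUE
  })

setClassUnion("EFSProtocolOrNULL", c("EFSProtocol", "NULL"))

## ---------------------------------------------------------------------------
## GeneratorConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic ICC-DMP recording generator
#'
#' Bundles every parameter of the synthetic-recording generator: acquisition
#' geometry (pixel size, frame rate, duration), cell geometry (spindle length
#' and width), the firing-site model, per-event kinetic parameters, imaging
#' noise, optional rigid drift and an optional [EFSProtocol()].
#'
#' `nSites` is either a fixed positive integer or a sampling rule
#' `list(rule = "clamped_poisson", mean, min, max)`; the default draws
#' Poisson(mean 5.2) counts clamped to `[1, 13]`, matching the range of
#' firing sites reported for ICC-DMP.
#'
#' Per-event amplitude, duration (FDHM), spatial spread and velocity are
#' drawn from lognormal distributions whose means are the configured values;
#' `ampCv` controls amplitude dispersion and `kineticCv` the kinetic
#' parameters.
#'
#' @param pixelSize micrometres per pixel (> 0).
#' @param frameRate acquisition rate, frames per second (> 0).
#' @param duration recording length in seconds.
#' @param cellLength,cellWidth spindle cell dimensions in micrometres.
#' @param nSites fixed integer site count, or a clamped-Poisson rule (see
#'   Details).
#' @param cellRate total event rate of the cell in events per second, shared
#'   equally among its firing sites.
#' @param ampMean mean event peak amplitude, dF/F0 units.
#' @param ampCv coefficient of variation of per-event amplitudes.
#' @param fdhm mean event full duration at half maximum, milliseconds; must
#'   exceed two frame periods.
#' @param spread mean spatial spread (total half-maximum extent) per event,
#'   micrometres; must be at least one pixel.
#' @param velocity mean propagation velocity, micrometres per second.
#' @param kineticCv coefficient of variation of per-event FDHM, spread and
#'   velocity.
#' @param riseMs linear rise time of the event kernel, milliseconds.
#' @param edgeSigmaUm Gaussian sigma (micrometres) of the spatial footprint
#'   edges flanking the propagating plateau.
#' @param minSiteSepUm minimum separation between firing sites along the
#'   centerline; default twice the site-clustering linkage distance so that
#'   ground-truth sites are resolvable by construction.
#' @param siteMarginUm sites are kept at least this far from the cell tips.
#' @param noiseSd Gaussian photon-noise SD in dF/F0 units (scaled by
#'   `baselineF0` in counts).
#' @param baselineF0 baseline fluorescence inside the cell, camera counts.
#' @param background intensity outside the cell, camera counts.
#' @param drift rigid per-frame drift rule: `list(type = "none")` or
#'   `list(type = "linear", dxPerFrame, dyPerFrame)` (pixels per frame;
#'   applied as accumulated integer translations).
#' @param efs an [EFSProtocol()] or `NULL` for an unstimulated recording.
#' @param seed integer seed making a simulated recording reproducible.
#' @return A `GeneratorConfig` object.
#' @seealso [presetConfig()], [simulateRecording()]
#' @examples
#' cfg <- GeneratorConfig(duration = 10, nSites = 3, seed = 1)
#' cfg
#' @export
GeneratorConfig <- function(pixelSize = 0.5, frameRate = 33, duration = 20,
                            cellLength = 80, cellWidth = 6,
                            nSites = list(rule = "clamped_poisson",
                                          mean = 5.2, min = 1, max = 13),
                            cellRate = 1.05, ampMean = 0.8, ampCv = 0.3,
                            fdhm = 189, spread = 11.1, velocity = 71.4,
                            kineticCv = 0.3, riseMs = 30,
                            edgeSigmaUm = 1.0, minSiteSepUm = 10,
                            siteMarginUm = 2, noiseSd = 0.05,
                            baselineF0 = 1000, background = 50,
                            drift = list(type = "none"),
                            efs = NULL, seed = 1L) {
  if (is.numeric(nSites) && length(nSites) == 1L)
    nSites <- list(rule = "fixed", n = as.integer(nSites))
  new("GeneratorConfig", pixelSize = pixelSize, frameRate = frameRate,
      duration = duration, cellLength = cellLength, cellWidth = cellWidth,
      nSites = nSites, cellRate = cellRate, ampMean = ampMean, ampCv = ampCv,
      fdhm = fdhm, spread = spread, velocity = velocity,
      kineticCv = kineticCv, riseMs = riseMs, edgeSigmaUm = edgeSigmaUm,
      minSiteSepUm = minSiteSepUm, siteMarginUm = siteMarginUm,
      noiseSd = noiseSd, baselineF0 = baselineF0, background = background,
      drift = drift, efs = efs, seed = as.integer(seed))
}

#' @rdname GeneratorConfig
#' @export
setClass("GeneratorConfig",
  representation(pixelSize = "numeric", frameRate = "numeric",
                 duration = "numeric", cellLength = "numeric",
                 cellWidth = "numeric", nSites = "list",
                 cellRate = "numeric", ampMean = "numeric", ampCv = "numeric",
                 fdhm = "numeric", spread = "numeric", velocity = "numeric",
                 kineticCv = "numeric", riseMs = "numeric",
                 edgeSigmaUm = "numeric", minSiteSepUm = "numeric",
                 siteMarginUm = "numeric", noiseSd = "numeric",
                 baselineF0 = "numeric", background = "numeric",
                 drift = "list", efs = "EFSProtocolOrNULL",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
    if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
    if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
    if (object@cellLength <= 0 || object@cellWidth <= 0)
      msg <- c(msg, "cell dimensions must be > 0")
    ns <- object@nSites
    if (identical(ns$rule, "fixed")) {
      if (is.null(ns$n) || ns$n < 1)
        msg <- c(msg, "fixed 'nSites' must be >= 1")
    } else if (identical(ns$rule, "clamped_poisson")) {
      if (is.null(ns$mean) || is.null(ns$min) || is.null(ns$max) ||
          ns$min < 1 || ns$min > ns$max)
        msg <- c(msg, "clamped_poisson rule needs mean, min >= 1, max >= min")
    } else {
      msg <- c(msg, "unknown nSites rule (use 'fixed' or 'clamped_poisson')")
    }
    if (object@cellRate < 0) msg <- c(msg, "'cellRate' must be >= 0")
    if (object@ampMean <= 0) msg <- c(msg, "'ampMean' must be > 0")
    if (object@fdhm <= 2000 / object@frameRate)
      msg <- c(msg, "'fdhm' must exceed two frame periods")
    if (object@fdhm <= object@riseMs / 2)
      msg <- c(msg, "'fdhm' must exceed half the rise time")
    if (object@spread < object@pixelSize)
      msg <- c(msg, "'spread' must be >= pixelSize")
    if (object@velocity <= 0) msg <- c(msg, "'velocity' must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (object@baselineF0 <= 0) msg <- c(msg, "'baselineF0' must be > 0")
    if (!is.null(object@efs)) {
      end <- object@efs@onset + object@efs@trainDuration
      if (end > object@duration)
        msg <- c(msg, "EFS train must end within the recording duration")
    }
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## CellGeometry
## ---------------------------------------------------------------------------

#' Synthetic cell geometry
#'
#' Geometry of one simulated spindle-shaped cell inside its imaging frame:
#' the binary mask, the (horizontal) centerline and the firing-site positions
#' along it. Produced by [makeCell()]; consumed by [sampleEventTrains()] and
#' [renderMovie()]. Rows/columns are 1-based internally; exported ROI
#' coordinates are 0-based.
#'
#' @slot mask logical matrix (rows x columns), `TRUE` inside the cell.
#' @slot centerRow row index of the centerline.
#' @slot centerCols column indices of the ordered centerline, one per bin.
#' @slot sitePositionsUm firing-site positions, micrometres from bin 0.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("CellGeometry",
  representation(mask = "matrix", centerRow = "integer",
                 centerCols = "integer", sitePositionsUm = "numeric",
                 pixelSize = "numeric"))

## ---------------------------------------------------------------------------
## CalciumMovie
## ---------------------------------------------------------------------------

#' Calibrated fluorescence image stack
#'
#' A single-channel fluorescence movie as a 3-D array (rows x columns x
#' frames, camera counts) carrying its acquisition calibration: frame rate
#' (frames/s) and pixel size (um/pixel). All values must be finite and
#' non-negative and the movie must have at least two frames.
#'
#' @param intensity numeric 3-D array, `dim = c(rows, cols, frames)`.
#' @param frameRate frames per second.
#' @param pixelSize micrometres per pixel.
#' @return A `CalciumMovie`.
#' @seealso [stabilizeMovie()], [buildSTMap()], [readMovie()]
#' @examples
#' mv <- CalciumMovie(array(100, c(8, 8, 4)), frameRate = 33, pixelSize = 0.5)
#' nFrames(mv)
#' @export
CalciumMovie <- function(intensity, frameRate, pixelSize) {
  new("CalciumMovie", intensity = intensity, frameRate = frameRate,
      pixelSize = pixelSize)
}

#' @rdname CalciumMovie
#' @export
setClass("CalciumMovie",
  representation(intensity = "array", frameRate = "numeric",
                 pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@intensity)
    if (length(d) != 3L)
      msg <- c(msg, "'intensity' must be a 3-D array (rows, cols, frames)")
    else if (d[3] < 2L)
      msg <- c(msg, "movie must have at least 2 frames")
    if (!all(is.finite(object@intensity)) || any(object@intensity < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
    if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## CellROI
## ---------------------------------------------------------------------------

#' Whole-cell region of interest
#'
#' A whole-cell ROI: a simple (non-self-intersecting) polygon outlining the
#' cell plus an ordered centerline running from one cell end to the other.
#' Coordinates are 0-based pixel coordinates, columns `x` (image column) and
#' `y` (image row), matching the on-disk JSON representation
#' ([readROI()]/[writeROI()]).
#'
#' @param polygon numeric matrix (vertices x 2, columns x/y).
#' @param centerline numeric matrix (points x 2, columns x/y), ordered from
#'   one cell end to the other.
#' @param pixelSize micrometres per pixel; used to validate the minimum
#'   centerline length of 4 um.
#' @return A `CellROI`.
#' @examples
#' poly <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 4, 4))
#' cl <- cbind(x = 0:10, y = rep(2, 11))
#' CellROI(poly, cl, pixelSize = 0.5)
#' @export
CellROI <- function(polygon, centerline, pixelSize = 1) {
  polygon <- as.matrix(polygon)
  centerline <- as.matrix(centerline)
  colnames(polygon) <- colnames(centerline) <- c("x", "y")
  new("CellROI", polygon = polygon, centerline = centerline,
      pixelSize = pixelSize)
}

#' @rdname CellROI
#' @export
setClass("CellROI",
  representation(polygon = "matrix", centerline = "matrix",
                 pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@polygon) != 2L || nrow(object@polygon) < 3L)
      msg <- c(msg, "'polygon' must be an n x 2 matrix with n >= 3")
    if (ncol(object@centerline) != 2L || nrow(object@centerline) < 2L)
      msg <- c(msg, "'centerline' must be an m x 2 matrix with m >= 2")
    else {
      seg <- diff(object@centerline)
      len <- sum(sqrt(rowSums(seg^2))) * object@pixelSize
      if (len < 4)
        msg <- c(msg, "centerline must be at least 4 um long")
    }
    if (nrow(object@polygon) >= 3L && .polygonSelfIntersects(object@polygon))
      msg <- c(msg, "'polygon' must be simple (non-self-intersecting)")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## STMap
## ---------------------------------------------------------------------------

#' Spatio-temporal map
#'
#' A kymograph of whole-cell Ca2+ activity: a matrix of \eqn{\Delta F/F_0}
#' values with one row per position bin along the cell's centerline (bin size
#' equals the movie pixel size) and one column per frame. Bin `k` (0-based)
#' covers position `k * binSize` micrometres from the `origin` end of the
#' centerline; frame `f` (0-based) is time `f / frameRate` seconds. Bins with
#' no contributing pixels are `NA`.
#'
#' @param dff numeric matrix (position bins x frames), dF/F0 units.
#' @param binSize micrometres per bin.
#' @param frameRate frames per second.
#' @param origin which centerline end is bin 0 (free-text label).
#' @return An `STMap`.
#' @seealso [buildSTMap()], [detectEvents()]
#' @export
STMap <- function(dff, binSize, frameRate, origin = "first centerline point") {
  new("STMap", dff = dff, binSize = binSize, frameRate = frameRate,
      origin = origin)
}

#' @rdname STMap
#' @export
setClass("STMap",
  representation(dff = "matrix", binSize = "numeric", frameRate = "numeric",
                 origin = "character"),
  validity = function(object) {
    msg <- character()
    if (any(is.nan(object@dff)) || any(is.infinite(object@dff)))
      msg <- c(msg, "dF/F0 values must be finite (or NA for missing bins)")
    if (object@binSize <= 0) msg <- c(msg, "'binSize' must be > 0")
    if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be > 0")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Methods
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("frameRate", "CalciumMovie", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "STMap", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CalciumMovie", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("nFrames", "CalciumMovie", function(x) dim(x@intensity)[3])
#' @rdname accessors
#' @export
setMethod("nFrames", "STMap", function(x) ncol(x@dff))
#' @rdname accessors
#' @export
setMethod("frames", "CalciumMovie", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("dff", "STMap", function(x) x@dff)
#' @rdname accessors
#' @export
setMethod("binSize", "STMap", function(x) x@binSize)

setMethod("show", "CalciumMovie", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "CalciumMovie: %d x %d px, %d frames (%.3g s at %g fps, %g um/px)\n",
    d[1], d[2], d[3], d[3] / object@frameRate, object@frameRate,
    object@pixelSize))
})

setMethod("show", "STMap", function(object) {
  cat(sprintf(
    "STMap: %d bins x %d frames (%.3g um/bin, %g fps); dF/F0 range [%.3g, %.3g]\n",
    nrow(object@dff), ncol(object@dff), object@binSize, object@frameRate,
    suppressWarnings(min(object@dff, na.rm = TRUE)),
    suppressWarnings(max(object@dff, na.rm = TRUE))))
})

setMethod("show", "EFSProtocol", function(object) {
  cat(sprintf(
    "EFSProtocol: onset %g s, %g s train at %g Hz; escape ~ TN(%g, %g) on [%g, %g] s, rho %g, post-escape gain %g\n",
    object@onset, object@trainDuration, object@pulseFreq, object@escapeMean,
    object@escapeSd, object@escapeMin, object@escapeMax, object@escapeRho,
    object@postEscapeGain))
})

setMethod("show", "GeneratorConfig", function(object) {
  ns <- object@nSites
  nsTxt <- if (identical(ns$rule, "fixed")) sprintf("%d fixed", ns$n) else
    sprintf("clamped Poisson(mean %g) on [%d, %d]", ns$mean,
            as.integer(ns$min), as.integer(ns$max))
  cat(sprintf("GeneratorConfig: %g s at %g fps, %g um/px\n",
              object@duration, object@frameRate, object@pixelSize))
  cat(sprintf("  cell %g x %g um; sites: %s; rate %g events/s\n",
              object@cellLength, object@cellWidth, nsTxt, object@cellRate))
  cat(sprintf("  events: amp %g dF/F0 (CV %g), FDHM %g ms, spread %g um, velocity %g um/s\n",
              object@ampMean, object@ampCv, object@fdhm, object@spread,
              object@velocity))
  cat(sprintf("  noise SD %g dF/F0, baseline %g counts, seed %d\n",
              object@noiseSd, object@baselineF0, object@seed))
  if (!is.null(object@efs)) show(object@efs)
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry: %d x %d px mask, %d centerline bins, %d firing site(s) at [%s] um\n",
    nrow(object@mask), ncol(object@mask), length(object@centerCols),
    length(object@sitePositionsUm),
    paste(sprintf("%.1f", object@sitePositionsUm), collapse = ", ")))
})

setMethod("show", "CellROI", function(object) {
  cat(sprintf("CellROI: %d-vertex polygon, %d-point centerline\n",
              nrow(object@polygon), nrow(object@centerline)))
})
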