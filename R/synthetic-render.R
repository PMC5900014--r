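#' @include AllClasses.R synthetic-events.R
NULL

## Temporal event kernel, unit peak: linear rise over riseS seconds, then
## exponential decay with time constant tau chosen by the caller so the
## half-maximum width of the full trace equals the event's FDHM.
.temporalKernel <- function(s, riseS, tau) {
  out <- numeric(length(s))
  up <- s >= 0 & s < riseS
  out[up] <- s[up] / riseS
  dn <- s >= riseS
  out[dn] <- exp(-(s[dn] - riseS) / tau)
  out
}

## Ground-truth dF/F0 ST matrix (bins x frames) for a set of events.
## Spatial model per event: a plateau of full activation grows from the
## initiation locus in the event's direction, its front advancing at the
## event's velocity, flanked by Gaussian edges (sigma edgeSigmaUm); the
## plateau stops when the total half-maximum extent equals the spread.
## Each position experiences the temporal kernel delayed by its distance
## from the origin over the velocity (a travelling wave).
.eventDffMatrix <- function(events, nbins, config) {
  bs <- config@pixelSize
  fr <- config@frameRate
  nT <- as.integer(round(config@duration * fr))
  riseS <- config@riseMs / 1000
  sig <- config@edgeSigmaUm
  edgeHalf <- sig * sqrt(2 * log(2))
  D <- matrix(0, nbins, nT)
  truncated <- 0L
  pos <- (seq_len(nbins) - 1) * bs
  tf <- (seq_len(nT) - 1) / fr
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    tau <- (ev$fdhm_ms / 1000 - riseS / 2) / log(2)
    Lw <- max(ev$spread_um - 2 * edgeHalf, 0)
    u <- ev$direction * (pos - ev$site_pos_um)
    keep <- u >= -2.8 * sig & u <= Lw + 2.8 * sig
    if (min(u) > -2.8 * sig || max(u) < Lw + 2.8 * sig)
      truncated <- truncated + 1L
    kk <- which(keep)
    if (!length(kk)) next
    uu <- u[kk]
    W <- ifelse(uu < 0, exp(-uu^2 / (2 * sig^2)),
                ifelse(uu <= Lw, 1, exp(-(uu - Lw)^2 / (2 * sig^2))))
    delay <- pmin(pmax(uu, 0), Lw) / ev$velocity_um_s
    f0 <- max(1L, as.integer(floor(ev$t_init_s * fr)) + 1L)
    f1 <- min(nT, as.integer(ceiling((ev$t_init_s + max(delay) + riseS +
                                        9 * tau) * fr)) + 1L)
    if (f1 < f0) next
    ff <- f0:f1
    S <- outer(delay, tf[ff], function(d, t) t - ev$t_init_s - d)
    D[kk, ff] <- D[kk, ff] +
      ev$amplitude_dff * W * .temporalKernel(S, riseS, tau)
  }
  attr(D, "truncated") <- truncated
  D
}

## Integer rigid translation of a matrix, exposed borders filled with `fill`.
.translateMatrix <- function(m, dy, dx, fill) {
  if (dy == 0 && dx == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dy
  cs <- seq_len(nc) - dx
  okR <- rs >= 1 & rs <= nr
  okC <- cs >= 1 & cs <= nc
  out[okR, okC] <- m[rs[okR], cs[okC]]
  out
}

#' Render a synthetic recording to an image stack
#'
#' Rasterizes a [GroundTruth-class] event ledger onto the cell geometry as a
#' calibrated 16-bit image stack. Each event contributes a travelling-wave
#' kernel: temporally, a linear rise over `riseMs` followed by an
#' exponential decay whose time constant is set so the trace's width at half
#' maximum equals the event's FDHM; spatially, a fully activated plateau
#' flanked by Gaussian edges whose leading edge advances from the initiation
#' locus at the event's velocity until the total half-maximum extent equals
#' the event's spread. Pixel intensities are
#' `baselineF0 * (1 + dF/F0)` inside the mask and `background` outside, with
#' additive Gaussian noise of SD `noiseSd * baselineF0`, optional rigid
#' integer drift per frame, clipping at 0 and quantization to 16-bit counts.
#' Events whose spatial kernel reaches past the cell tips are truncated at
#' the mask edge and counted in the log attribute (not an error).
#'
#' @param cell a [CellGeometry-class].
#' @param truth a [GroundTruth-class] from [sampleEventTrains()].
#' @param config the matching [GeneratorConfig()].
#' @param seed optional seed for the noise draw; `NULL` uses the current RNG
#'   state.
#' @return A [CalciumMovie()] with attributes `"log"` (character vector) on
#'   the returned object's `metadata`-like attribute accessed via
#'   `attr(x, "log")`.
#' @examples
#' cfg <- GeneratorConfig(duration = 3, nSites = 1, cellRate = 0.5,
#'                        noiseSd = 0, seed = 7)
#' sim <- simulateRecording(cfg)
#' sim$movie
#' @export
renderMovie <- function(cell, truth, config, seed = NULL) {
  withSeed(seed, {
    nbins <- length(cell@centerCols)
    events <- truth@events
    if (nrow(events)) {
      events$site_pos_um <- truth@sites$position_um[events$site_id]
    } else {
      events <- cbind(.emptyEvents(), site_pos_um = numeric())
    }
    D <- .eventDffMatrix(events, nbins, config)
    nT <- ncol(D)
    nr <- nrow(cell@mask); nc <- ncol(cell@mask)

    maskIdx <- which(cell@mask)
    maskCol <- ((maskIdx - 1L) %/% nr) + 1L
    maskBin <- match(maskCol, cell@centerCols)

    A <- array(config@background, c(nr, nc, nT))
    M <- config@baselineF0 * (1 + D[maskBin, , drop = FALSE])
    idx <- rep(maskIdx, times = nT) +
      rep((seq_len(nT) - 1L) * (nr * nc), each = length(maskIdx))
    A[idx] <- M

    logTxt <- character()
    if (attr(D, "truncated") > 0L)
      logTxt <- c(logTxt, sprintf(
        "%d event(s) truncated at the mask edge", attr(D, "truncated")))

    dr <- config@drift
    if (!identical(dr$type, "none")) {
      if (!identical(dr$type, "linear"))
        stop("unknown drift type '", dr$type, "' (use 'none' or 'linear')")
      for (f in seq_len(nT)) {
        dy <- as.integer(round((f - 1) * dr$dyPerFrame))
        dx <- as.integer(round((f - 1) * dr$dxPerFrame))
        if (dy != 0 || dx != 0)
          A[, , f] <- .translateMatrix(A[, , f], dy, dx, config@background)
      }
      logTxt <- c(logTxt, "linear rigid drift applied")
    }

    if (config@noiseSd > 0)
      A <- A + rnorm(length(A), 0, config@noiseSd * config@baselineF0)
    A[A < 0] <- 0
    A <- round(A)
    A[A > 65535] <- 65535

    mv <- CalciumMovie(A, frameRate = config@frameRate,
                       pixelSize = config@pixelSize)
    attr(mv, "log") <- logTxt
    mv
  })
}

#' Simulate one complete synthetic recording
#'
#' Convenience wrapper chaining [makeCell()], [sampleEventTrains()] and
#' [renderMovie()] under the config's seed, so identical `(config, seed)`
#' yield bit-identical movies and ground truth.
#'
#' @param config a [GeneratorConfig()].
#' @param seed integer seed; defaults to `config@seed`.
#' @return A list with elements `movie` ([CalciumMovie()]), `roi`
#'   ([CellROI()]), `truth` ([GroundTruth-class]) and `cell`
#'   ([CellGeometry-class]).
#' @examples
#' sim <- simulateRecording(presetConfig("baseline", duration = 5, seed = 3))
#' sim$truth
#' @export
simulateRecording <- function(config, seed = config@seed) {
  withSeed(seed, {
    cell <- makeCell(config)
    truth <- sampleEventTrains(cell, config)
    movie <- renderMovie(cell, truth, config)
    list(movie = movie, roi = cellROI(cell), truth = truth, cell = cell)
  })
}
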