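#' @include AllClasses.R
NULL

## Interpolated time (s) at which the trace crosses `half`, between frame
## indices j and j+1 (1-based); dt in seconds.
.crossTime <- function(trace, j, half, dt) {
  y0 <- trace[j]; y1 <- trace[j + 1L]
  (j - 1L) * dt + dt * (half - y0) / (y1 - y0)
}

.measureOne <- function(cells, x, binSize, dt) {
  vals <- x[cells]
  ## amplitude and peak cell: earliest frame, then lowest bin, on ties
  amp <- max(vals)
  mx <- which(vals == amp)
  mx <- mx[order(cells[mx, 2L], cells[mx, 1L])][1L]
  peakBin <- cells[mx, 1L]
  peakFrame <- cells[mx, 2L]

  ## initiation: the bin whose trace first reaches half-maximum within the
  ## footprint (the origin of a travelling wave rises first). Several bins
  ## can first exceed half on the same frame; their sub-frame crossing
  ## times, linearly interpolated from the previous frame, break the tie.
  ## Lowest bin on exact ties.
  f0 <- min(cells[, 2L])
  halfInit <- amp / 2
  crossIdx <- which(vals >= halfInit)
  if (length(crossIdx)) {
    fCross <- min(cells[crossIdx, 2L])
    cand <- crossIdx[cells[crossIdx, 2L] == fCross]
    tSub <- vapply(cand, function(i) {
      b <- cells[i, 1L]
      if (fCross == 1L) return(0)
      prev <- x[b, fCross - 1L]
      if (!is.finite(prev) || prev >= halfInit) return(0)
      (halfInit - prev) / (x[b, fCross] - prev)
    }, numeric(1))
    first <- cand[order(tSub, cells[cand, 1L])][1L]
  } else {
    cand <- which(cells[, 2L] == f0)
    first <- cand[order(-vals[cand], cells[cand, 1L])][1L]
  }
  initBin <- cells[first, 1L]

  ## FDHM at the peak bin with linearly interpolated half crossings
  half <- amp / 2
  trace <- x[peakBin, ]
  trace[is.na(trace)] <- -Inf
  nT <- length(trace)
  l <- peakFrame
  while (l > 1L && trace[l - 1L] >= half) l <- l - 1L
  r <- peakFrame
  while (r < nT && trace[r + 1L] >= half) r <- r + 1L
  tLeft <- if (l > 1L) .crossTime(trace, l - 1L, half, dt) else (l - 1L) * dt
  tRight <- if (r < nT) .crossTime(trace, r, half, dt) else (r - 1L) * dt
  fdhm <- (tRight - tLeft) * 1000

  ## spatial spread: total half-maximum extent of the footprint
  hm <- cells[vals >= half, , drop = FALSE]
  spread <- (max(hm[, 1L]) - min(hm[, 1L]) + 1L) * binSize
  sgn <- hm[, 1L] - initBin
  far <- which.max(abs(sgn))
  travel <- abs(sgn[far]) * binSize

  ## velocity: least-squares slope of the leading half-max edge (signed
  ## distance of the farthest half-max bin from the initiation bin) over
  ## the frames from initiation to peak
  nFrames <- length(unique(cells[, 2L]))
  velocity <- NA_real_
  velSigned <- NA_real_
  if (nFrames < 3L) {
    velocity <- 0
    velSigned <- 0
  } else if (peakFrame > f0) {
    ## propagation side: sign of the farthest half-max displacement over
    ## the whole footprint (the leading edge; the trailing Gaussian margin
    ## is not propagation)
    dirSgn <- if (length(sgn) && sgn[far] < 0L) -1L else 1L
    ts <- numeric(); es <- numeric()
    for (f in f0:peakFrame) {
      sel <- cells[, 2L] == f & vals >= half
      if (!any(sel)) next
      s <- (cells[sel, 1L] - initBin) * dirSgn
      s <- s[s >= 0L]
      if (!length(s)) next
      ts <- c(ts, (f - 1L) * dt)
      es <- c(es, dirSgn * max(s) * binSize)
    }
    ## keep only the advance phase: once the edge has reached its farthest
    ## position it stalls, and stalled frames (e.g. when a second merged
    ## event delays the peak) would dilute the slope of the front
    if (length(ts) >= 2L) {
      stall <- which.max(es * dirSgn)
      ts <- ts[seq_len(stall)]
      es <- es[seq_len(stall)]
    }
    if (length(ts) >= 2L) {
      velSigned <- stats::cov(ts, es) / stats::var(ts)
      velocity <- abs(velSigned)
    }
  }

  data.frame(
    t_init_s = (f0 - 1L) * dt,
    p_init_um = (initBin - 1L) * binSize,
    t_peak_s = (peakFrame - 1L) * dt,
    p_peak_um = (peakBin - 1L) * binSize,
    amplitude_dff = amp,
    fdhm_ms = fdhm,
    spread_um = spread,
    travel_um = travel,
    velocity_um_s = velocity,
    velocity_signed_um_s = velSigned,
    n_frames = nFrames,
    n_bins = length(unique(cells[, 1L])))
}

#' Measure per-event metrics on detected footprints
#'
#' Computes the standard per-event quantities for each detected footprint:
#'
#' * `amplitude_dff` -- peak \eqn{\Delta F/F_0} over the footprint (on the
#'   median-centred map).
#' * `t_peak_s`/`p_peak_um` -- time/position of that peak (earliest frame,
#'   then lowest bin, on exact ties).
#' * `t_init_s`/`p_init_um` -- initiation: the earliest footprint frame,
#'   and the bin whose trace first reaches half maximum within the
#'   footprint (the origin of a travelling wave rises first; robust to
#'   single-cell noise at the detection fringe).
#' * `fdhm_ms` -- full duration at half maximum of the peak-bin trace, the
#'   two half crossings linearly interpolated between frames.
#' * `spread_um` -- total half-maximum spatial extent: `(max bin - min bin
#'   + 1) * binSize` over footprint cells with value >= half the amplitude.
#'   (`travel_um`, the distance from initiation to the farthest half-max
#'   bin, is reported alongside as the propagated-path alternative.)
#' * `velocity_um_s` -- magnitude of the least-squares slope of the leading
#'   half-max edge position versus time from initiation to peak
#'   (`velocity_signed_um_s` keeps the direction). Events spanning fewer
#'   than 3 frames report 0; events with fewer than two usable edge frames
#'   report `NA`.
#'
#' @param det a `"CaEventFootprints"` from [detectEvents()], or a bare list
#'   of footprint matrices.
#' @param stmap the [STMap()] the footprints were detected on.
#' @return A data.frame with one row per event (columns above plus `id` and
#'   a `site_id` placeholder), ordered by `t_init_s`.
#' @seealso [detectEvents()], [clusterSites()]
#' @export
measureEvents <- function(det, stmap) {
  fps <- if (inherits(det, "CaEventFootprints")) det$footprints else det
  dt <- 1 / stmap@frameRate
  if (!length(fps)) {
    out <- .measureOne(cbind(bin = 1L, frame = 1L), matrix(0, 1, 1),
                       stmap@binSize, dt)[0, ]
    out$id <- integer()
    out$site_id <- integer()
    return(out)
  }
  ## measure on the same median-centred dF/F0 as detection: the percentile
  ## F0 leaves the quiescent level of a noisy trace slightly above zero,
  ## which would otherwise bias amplitudes up and widen half-max crossings
  x <- stmap@dff
  center <- apply(x, 1L, stats::median, na.rm = TRUE)
  center[!is.finite(center)] <- 0
  x <- x - center
  rows <- lapply(fps, .measureOne, x = x,
                 binSize = stmap@binSize, dt = dt)
  out <- do.call(rbind, rows)
  out <- out[order(out$t_init_s, out$p_init_um), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$site_id <- NA_integer_
  rownames(out) <- NULL
  out[, c("id", "site_id", setdiff(names(out), c("id", "site_id")))]
}
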