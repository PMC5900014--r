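#' @include AllClasses.R utils.R
NULL

#' Baseline fluorescence of a bin trace
#'
#' Estimates the baseline fluorescence \eqn{F_0} of one position bin as the
#' 10th percentile of its intensity trace -- over the whole recording, or
#' over a supplied frame window (typically the pre-stimulus epoch when an
#' EFS protocol is known). A percentile baseline resists contamination by
#' frequent transients, which a mean would not. The result is floored at 1
#' count so \eqn{\Delta F/F_0} stays defined; an all-zero trace triggers a
#' warning.
#'
#' @param trace numeric vector of intensities (counts) for one bin.
#' @param frames optional integer vector of 1-based frame indices to
#'   restrict the estimate to (e.g. the pre-EFS window).
#' @param probs percentile used for the baseline (default 0.1).
#' @return A single positive number.
#' @examples
#' computeF0(rep(100, 300))                   # constant trace -> 100
#' computeF0(c(rep(100, 290), rep(200, 10)))  # transients ignored -> 100
#' @export
computeF0 <- function(trace, frames = NULL, probs = 0.1) {
  if (!is.null(frames)) trace <- trace[frames]
  trace <- trace[!is.na(trace)]
  if (length(trace) < 33)
    stop("F0 estimation needs at least 33 frames of data per bin")
  f0 <- as.numeric(stats::quantile(trace, probs, names = FALSE))
  if (f0 < 1) {
    if (all(trace == 0)) warning("all-zero bin; F0 floored at 1 count")
    f0 <- 1
  }
  f0
}

#' Build a spatio-temporal map from a movie and a whole-cell ROI
#'
#' Collapses a (stabilized) movie onto the cell's centerline: every
#' in-polygon pixel is assigned to its nearest centerline point, each
#' centerline position's trace is the mean over its assigned pixels
#' (transverse collapse by the mean keeps amplitudes comparable across cell
#' widths), and each trace is normalized to \eqn{\Delta F/F_0 = (F - F_0) /
#' F_0} with \eqn{F_0} from [computeF0()]. One map row per centerline point
#' (bin size = pixel size), one column per frame. Centerline positions with
#' no assigned pixels become `NA` rows.
#'
#' @param movie a [CalciumMovie()] (stabilize first if the tissue moved).
#' @param roi a [CellROI()] in 0-based pixel coordinates.
#' @param f0Frames optional frame window forwarded to [computeF0()]
#'   (e.g. pre-EFS frames).
#' @return An [STMap()].
#' @examples
#' sim <- simulateRecording(GeneratorConfig(duration = 2, nSites = 1,
#'                                          noiseSd = 0, seed = 1))
#' stm <- buildSTMap(sim$movie, sim$roi)
#' stm
#' @export
buildSTMap <- function(movie, roi, f0Frames = NULL) {
  A <- movie@intensity
  nr <- dim(A)[1]; nc <- dim(A)[2]; nT <- dim(A)[3]
  poly <- roi@polygon
  cl <- roi@centerline
  if (min(poly[, "x"]) < -1 || max(poly[, "x"]) > nc ||
      min(poly[, "y"]) < -1 || max(poly[, "y"]) > nr)
    stop("ROI polygon extends outside the movie frame")

  ## candidate pixels: bounding box of the polygon (0-based centres)
  cMin <- max(0L, floor(min(poly[, "x"])))
  cMax <- min(nc - 1L, ceiling(max(poly[, "x"])))
  rMin <- max(0L, floor(min(poly[, "y"])))
  rMax <- min(nr - 1L, ceiling(max(poly[, "y"])))
  grid <- expand.grid(x = cMin:cMax, y = rMin:rMax)
  inside <- pointInPolygon(grid$x, grid$y, poly[, "x"], poly[, "y"])
  px <- grid[inside, , drop = FALSE]
  if (nrow(px) == 0L) stop("ROI polygon contains no pixel centres")

  ## nearest centerline point per pixel
  nb <- nrow(cl)
  d2 <- outer(px$x, cl[, "x"], "-")^2 + outer(px$y, cl[, "y"], "-")^2
  bin <- max.col(-d2, ties.method = "first")

  ## pixels x frames intensity matrix via flat indexing (1-based rows/cols)
  flat <- (px$x) * nr + (px$y + 1L)
  P <- vapply(seq_len(nT),
              function(f) A[flat + (f - 1L) * nr * nc],
              numeric(nrow(px)))

  counts <- tabulate(bin, nbins = nb)
  sums <- rowsum(P, group = bin, reorder = TRUE)
  F <- matrix(NA_real_, nb, nT)
  present <- sort(unique(bin))
  F[present, ] <- sums / counts[present]

  D <- matrix(NA_real_, nb, nT)
  for (k in present) {
    f0 <- computeF0(F[k, ], frames = f0Frames)
    D[k, ] <- (F[k, ] - f0) / f0
  }
  STMap(D, binSize = movie@pixelSize, frameRate = movie@frameRate)
}
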