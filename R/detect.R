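#' @include AllClasses.R
NULL

## Variance of a standard normal truncated above at its 75th percentile;
## dividing the truncated SD by sqrt of this makes the robust noise
## estimate consistent for Gaussian noise (cf. MAD's 1.4826).
.truncSdFactor <- local({
  b <- qnorm(0.75)
  lam <- dnorm(b) / 0.75
  sqrt(1 - b * lam - lam^2)
})

## Robust noise SD of dF/F0 values: SD after excluding the top 25%
## (transient-dominated), rescaled for the truncation bias.
estimateNoiseSigma <- function(x, warn = TRUE) {
  v <- x[is.finite(x)]
  cut <- stats::quantile(v, 0.75, names = FALSE)
  s <- stats::sd(v[v <= cut]) / .truncSdFactor
  if (!is.finite(s) || s < 1e-6) {
    if (warn) warning("degenerate noise estimate; sigma floored at 1e-6")
    s <- 1e-6
  }
  s
}

## Per-bin noise SDs. The transverse collapse averages a different number
## of pixels in every bin of a spindle-shaped cell (few at the tapered
## tips, many mid-cell), so map noise is strongly heteroscedastic; a
## per-bin estimate keeps the false-positive rate uniform along the cell.
.binSigma <- function(x) {
  s <- apply(x, 1L, function(r) {
    if (all(!is.finite(r))) return(NA_real_)
    estimateNoiseSigma(r, warn = FALSE)
  })
  if (all(!is.finite(s)) || all(s[is.finite(s)] <= 1e-6))
    warning("degenerate noise estimate; sigma floored at 1e-6")
  s[!is.finite(s)] <- Inf  # all-NA bins never become foreground
  s
}

## 8-connected component labelling by iterative minimum-label propagation.
## Deterministic: every component ends up labelled by its smallest cell
## index. Returns an integer matrix, 0 = background.
labelComponents <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  nFg <- length(idx)
  if (!nFg) return(lab)
  lookup <- integer(nr * nc)
  lookup[idx] <- seq_len(nFg)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ## positions (within the fg set) of each cell's 8 neighbours, 0 if absent
  offs <- cbind(dy = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                dx = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
  nb <- matrix(0L, nFg, 8L)
  for (j in 1:8) {
    rr <- r + offs[j, 1L]
    ccj <- cc + offs[j, 2L]
    ok <- rr >= 1L & rr <= nr & ccj >= 1L & ccj <= nc
    nb[ok, j] <- lookup[(ccj[ok] - 1L) * nr + rr[ok]]
  }
  ## iterative minimum-label propagation over the sparse adjacency;
  ## converges to the smallest cell index of each component
  l <- seq_len(nFg)
  repeat {
    m <- l
    for (j in 1:8) {
      nbj <- nb[, j]
      has <- nbj > 0L
      m[has] <- pmin(m[has], l[nbj[has]])
    }
    if (identical(m, l)) break
    l <- m
  }
  lab[idx] <- idx[l]
  lab
}

## Find a saddle cut along one axis of a footprint: the first interior
## local minimum of the per-coordinate max profile that dips below half of
## both flanking peaks. Returns the cut coordinate or NA.
.findSaddle <- function(coord, vals) {
  u <- sort(unique(coord))
  if (length(u) < 3L) return(NA_integer_)
  prof <- vapply(u, function(k) max(vals[coord == k]), 0)
  n <- length(prof)
  for (i in 2:(n - 1L)) {
    if (prof[i] < prof[i - 1L] && prof[i] <= prof[i + 1L]) {
      pl <- max(prof[1:(i - 1L)])
      pr <- max(prof[(i + 1L):n])
      if (prof[i] < 0.5 * pl && prof[i] < 0.5 * pr) return(u[i])
    }
  }
  NA_integer_
}

## Arrival-time watershed for near-simultaneous waves from neighbouring
## sites: a merged double wave has two local minima in the per-bin
## half-maximum arrival time with a late-arrival collision ridge between
## them. Returns a bin cut, or NA when no pair of origins at least
## minSepBins apart is separated by a ridge of at least minProm frames.
.findArrivalCut <- function(cells, vals, minProm = 2L, minSepBins = 10L) {
  half <- max(vals) / 2
  hm <- vals >= half
  if (!any(hm)) return(NA_integer_)
  bins <- sort(unique(cells[hm, 1L]))
  if (length(bins) < minSepBins) return(NA_integer_)
  arrival <- vapply(bins, function(b)
    min(cells[hm & cells[, 1L] == b, 2L]), integer(1))
  n <- length(arrival)
  best <- NA_integer_; bestQ <- -Inf
  for (i in 2:(n - 1L)) {
    aL <- min(arrival[1:(i - 1L)])
    aR <- min(arrival[(i + 1L):n])
    q <- min(arrival[i] - aL, arrival[i] - aR)
    if (q > bestQ) { bestQ <- q; best <- i }
  }
  if (bestQ < minProm) return(NA_integer_)
  oL <- bins[which.min(arrival[1:(best - 1L)])]
  oR <- bins[best + which.min(arrival[(best + 1L):n])]
  if (oR - oL < minSepBins) return(NA_integer_)
  bins[best]
}

## Recursively split a footprint into single events: at saddles that dip
## below half of both flanking peaks, along time (rapid successive events
## at one site) and along position (concurrent events at neighbouring
## sites whose footprints touch), and at arrival-time watersheds
## (simultaneous waves colliding between two origins). Splitting along
## both axes keeps one detection per event and makes the event count
## behave monotonically in the threshold.
.saddleSplit <- function(cells, vals, stmap) {
  cutT <- .findSaddle(cells[, 2L], vals)
  if (!is.na(cutT)) {
    left <- cells[, 2L] < cutT
  } else {
    cutS <- .findSaddle(cells[, 1L], vals)
    if (is.na(cutS)) cutS <- .findArrivalCut(cells, vals)
    if (is.na(cutS)) return(list(cells))
    left <- cells[, 1L] < cutS
  }
  c(.saddleSplit(cells[left, , drop = FALSE], vals[left], stmap),
    .saddleSplit(cells[!left, , drop = FALSE], vals[!left], stmap))
}

#' Detect Ca2+ events on a spatio-temporal map
#'
#' Segments supra-threshold transients on an ST map. The noise SD is
#' estimated robustly per position bin (SD of the bin's
#' \eqn{\Delta F/F_0} trace after excluding its top 25% of values,
#' corrected for truncation bias; per-bin because the transverse collapse
#' averages fewer pixels at the tapered cell tips, making map noise
#' heteroscedastic); each bin's trace is centred at its median (the
#' percentile baseline leaves quiescent \eqn{\Delta F/F_0} slightly above
#' zero on noisy data); centred cells above `thresholdK * sigma` are
#' foreground; 8-connected components in the
#' (bin, frame) lattice spanning at least `minFrames` distinct frames and
#' `minBins` distinct bins, and containing at least one cell reaching
#' `minPeakK * sigma` (a hysteresis-style peak criterion that rejects
#' threshold-flicker fragments shed by the tails of real transients),
#' become candidate events. Components are then recursively split into
#' single events: at temporal saddles below half of both flanking peaks
#' (rapid successive events at one site), at the analogous spatial
#' saddles (concurrent events at neighbouring sites), and at
#' arrival-time watersheds (simultaneous waves colliding between two
#' origins); fragments are re-checked against the size and peak minima.
#'
#' Event count is non-increasing in `thresholdK` (exactly so on
#' noise-free maps; under noise, sub-half saddles crossing the threshold
#' can occasionally nudge a count up by one). `NA` bins never enter a
#' footprint.
#'
#' @param stmap an [STMap()].
#' @param thresholdK detection threshold in noise SDs (default 3).
#' @param minFrames,minBins minimum temporal/spatial extent of an event in
#'   frames/bins (defaults 2 and 2).
#' @param sigma optional externally supplied noise SD (scalar, or one value
#'   per bin) overriding the robust estimate (e.g. from a quiescent
#'   window).
#' @param minPeakK peak criterion in noise SDs: a component must reach this
#'   level somewhere to count as an event (default `2 * thresholdK`, the
#'   usual dual-threshold arrangement).
#' @return A list of class `"CaEventFootprints"`: `footprints` (list of
#'   integer matrices with columns `bin`, `frame`, 1-based), `sigma`
#'   (median per-bin SD), `binSigma`, `threshold`.
#' @seealso [measureEvents()], [clusterSites()]
#' @examples
#' m <- matrix(0, 20, 40)
#' m[5:8, 10:14] <- 1
#' det <- detectEvents(STMap(m, 0.5, 33), sigma = 0.05)
#' length(det$footprints)
#' @export
detectEvents <- function(stmap, thresholdK = 3, minFrames = 2L,
                         minBins = 2L, sigma = NULL,
                         minPeakK = 2 * thresholdK) {
  x <- stmap@dff
  ## centre each bin at its median: the percentile F0 leaves the quiescent
  ## dF/F0 level slightly above zero on noisy data, which would silently
  ## lower the effective threshold
  center <- apply(x, 1L, stats::median, na.rm = TRUE)
  center[!is.finite(center)] <- 0
  xc <- x - center
  if (is.null(sigma)) sigma <- .binSigma(xc)
  if (length(sigma) != 1L && length(sigma) != nrow(x))
    stop("'sigma' must be a scalar or one value per bin")
  thr <- thresholdK * sigma
  fg <- !is.na(xc) & xc > thr  # thr recycles down columns (per-bin)
  lab <- labelComponents(fg)
  ids <- sort(unique(lab[lab > 0L]))
  sigPer <- if (length(sigma) == 1L) rep(sigma, nrow(x)) else sigma
  keep <- function(cells) {
    length(unique(cells[, 2L])) >= minFrames &&
      length(unique(cells[, 1L])) >= minBins &&
      max(xc[cells] / sigPer[cells[, 1L]]) >= minPeakK
  }
  footprints <- list()
  for (id in ids) {
    cells <- which(lab == id, arr.ind = TRUE)
    colnames(cells) <- c("bin", "frame")
    if (!keep(cells)) next
    vals <- x[cells]
    parts <- .saddleSplit(cells, vals, stmap)
    for (p in parts) if (keep(p)) footprints[[length(footprints) + 1L]] <- p
  }
  structure(list(footprints = footprints,
                 sigma = if (length(sigma) == 1L) sigma else
                   stats::median(sigma[is.finite(sigma)]),
                 binSigma = sigma, threshold = thr),
            class = "CaEventFootprints")
}

#' @export
print.CaEventFootprints <- function(x, ...) {
  cat(sprintf(
    "CaEventFootprints: %d event(s), sigma %.4g (median), threshold %.4g\n",
    length(x$footprints), x$sigma, stats::median(x$threshold)))
  invisible(x)
}
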