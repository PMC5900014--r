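#' @include AllClasses.R utils.R
NULL

## Draw a firing-site count from the configured rule.
sampleSiteCount <- function(config) {
  ns <- config@nSites
  if (identical(ns$rule, "fixed")) return(as.integer(ns$n))
  n <- rpois(1L, ns$mean)
  as.integer(min(max(n, ns$min), ns$max))
}

#' Generate the geometry of a synthetic spindle cell
#'
#' Builds a spindle-shaped (elliptical-profile) binary mask of the configured
#' length and width centred in an imaging frame with a 10-pixel margin, an
#' ordered horizontal centerline with one point per pixel step (one ST-map
#' bin each), and firing-site positions along the centerline.
#'
#' Site positions are uniform along the centerline subject to a minimum
#' separation (`minSiteSepUm`, default twice the site-clustering linkage
#' distance, so ground-truth sites are resolvable by construction) and an
#' end margin (`siteMarginUm`). If the drawn site count cannot be packed at
#' that separation it is reduced to the largest feasible count, with a
#' warning. A cell longer or wider than ~2000 pixels is rejected.
#'
#' @param config a [GeneratorConfig()].
#' @param seed optional integer seed; `NULL` uses (and advances) the current
#'   RNG state.
#' @return A [CellGeometry-class] object.
#' @examples
#' cell <- makeCell(GeneratorConfig(nSites = 3), seed = 1)
#' cell
#' @export
makeCell <- function(config, seed = NULL) {
  withSeed(seed, {
    px <- config@pixelSize
    margin <- 10L
    ncl <- round(config@cellLength / px)
    halfW <- config@cellWidth / 2 / px
    if (ncl > 2000 || 2 * halfW > 2000)
      stop("cell of ", config@cellLength, " x ", config@cellWidth,
           " um does not fit a reasonable frame at ", px, " um/px")
    nc <- as.integer(ncl + 2L * margin)
    nr <- as.integer(2L * ceiling(halfW) + 1L + 2L * margin)
    centerRow <- as.integer((nr + 1L) %/% 2L)
    centerCols <- as.integer(margin + seq_len(ncl))

    ## elliptical half-width profile; >= 0.51 px so the centerline row is
    ## always inside the mask, including at the tapered tips
    s <- (seq_len(ncl) - 0.5) / ncl
    wpx <- pmax(halfW * sqrt(pmax(0, 1 - (2 * s - 1)^2)), 0.51)
    mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(ncl)) {
      rows <- seq.int(ceiling(centerRow - wpx[i]), floor(centerRow + wpx[i]))
      mask[rows, centerCols[i]] <- TRUE
    }

    n <- sampleSiteCount(config)
    lo <- config@siteMarginUm
    hi <- config@cellLength - config@siteMarginUm
    sep <- config@minSiteSepUm
    nMax <- max(1L, as.integer(floor((hi - lo) / sep)) + 1L)
    if (n > nMax) {
      warning("site count ", n, " cannot be packed at ", sep,
              " um separation; reduced to ", nMax)
      n <- nMax
    }
    ## ordered uniforms on the slack interval + fixed separations gives the
    ## uniform distribution conditioned on all gaps >= sep
    slack <- (hi - lo) - (n - 1L) * sep
    u <- sort(runif(n, 0, slack))
    sites <- lo + u + (seq_len(n) - 1L) * sep

    new("CellGeometry", mask = mask, centerRow = centerRow,
        centerCols = centerCols, sitePositionsUm = sites, pixelSize = px)
  })
}

#' Whole-cell ROI of a synthetic cell
#'
#' Converts a [makeCell()] geometry into the [CellROI()] the analysis side
#' consumes: a polygon tightly outlining the mask (offset 0.4 px beyond the
#' outermost mask rows so pixel centres classify correctly) and the
#' centerline point list, both in 0-based pixel coordinates.
#'
#' @param cell a [CellGeometry-class].
#' @return A [CellROI()].
#' @export
cellROI <- function(cell) {
  cols <- cell@centerCols
  topR <- vapply(cols, function(c) min(which(cell@mask[, c])), 1L)
  botR <- vapply(cols, function(c) max(which(cell@mask[, c])), 1L)
  ## 0-based coordinates: x = col - 1, y = row - 1
  top <- cbind(x = cols - 1, y = topR - 1 - 0.4)
  bot <- cbind(x = rev(cols) - 1, y = rev(botR) - 1 + 0.4)
  poly <- rbind(cbind(x = cols[1] - 1 - 0.4, y = cell@centerRow - 1),
                top,
                cbind(x = cols[length(cols)] - 1 + 0.4, y = cell@centerRow - 1),
                bot)
  cl <- cbind(x = cols - 1, y = rep(cell@centerRow - 1, length(cols)))
  CellROI(poly, cl, pixelSize = cell@pixelSize)
}
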