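#' @include AllClasses.R utils.R
NULL

#' Ground truth of a synthetic recording
#'
#' The simulator's ledger for one cell: firing-site positions, every emitted
#' event with its kinetic parameters, and (when an EFS protocol is present)
#' the per-site escape latencies. Used as the oracle in recovery tests.
#'
#' @slot sites data.frame with `site_id`, `position_um`.
#' @slot events data.frame with `site_id`, `t_init_s`, `amplitude_dff`,
#'   `fdhm_ms`, `spread_um`, `velocity_um_s`, `direction` (+1 towards larger
#'   positions, -1 towards smaller).
#' @slot escape data.frame with `site_id`, `latency_s` (0 rows without EFS).
#' @export
setClass("GroundTruth",
  representation(sites = "data.frame", events = "data.frame",
                 escape = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d site(s), %d event(s)%s\n",
              nrow(object@sites), nrow(object@events),
              if (nrow(object@escape))
                sprintf(", escape latencies %s s",
                        paste(sprintf("%.2f", object@escape$latency_s),
                              collapse = "/")) else ""))
})

.emptyEvents <- function() {
  data.frame(site_id = integer(), t_init_s = numeric(),
             amplitude_dff = numeric(), fdhm_ms = numeric(),
             spread_um = numeric(), velocity_um_s = numeric(),
             direction = integer())
}

#' Sample stochastic event trains for a synthetic cell
#'
#' Draws per-site event trains. Outside any EFS suppression each site fires
#' as a homogeneous Poisson process at rate `cellRate / nSites` (the minimal
#' model for ongoing, uncoordinated transients). With an [EFSProtocol()],
#' each site draws an escape latency from the truncated normal
#' (`escapeMean`, `escapeSd`, `[escapeMin, escapeMax]`) -- latencies of sites
#' within one cell share the protocol's Gaussian-copula correlation
#' `escapeRho`, cells are independent -- and is silent during
#' `[onset, onset + latency)`. The site's first post-onset event occurs at
#' `onset + latency` (that event *is* the observable escape from
#' inhibition), after which firing continues as a Poisson process at
#' `postEscapeGain` times the basal rate until the end of the recording.
#'
#' Per-event amplitude, FDHM, spread and velocity are drawn from lognormal
#' distributions around the configured means (`ampCv`, `kineticCv`);
#' propagation direction is +/-1 with equal probability.
#'
#' @param cell a [CellGeometry-class] from [makeCell()].
#' @param config the [GeneratorConfig()] used to build `cell`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A [GroundTruth-class] object; events are sorted by `t_init_s`.
#' @examples
#' cfg <- GeneratorConfig(nSites = 2, duration = 10)
#' cell <- makeCell(cfg, seed = 1)
#' truth <- sampleEventTrains(cell, cfg, seed = 2)
#' truth
#' @export
sampleEventTrains <- function(cell, config, seed = NULL) {
  withSeed(seed, {
    sitesUm <- cell@sitePositionsUm
    n <- length(sitesUm)
    rate <- config@cellRate / n
    dur <- config@duration
    efs <- config@efs

    sites <- data.frame(site_id = seq_len(n), position_um = sitesUm)
    escape <- data.frame(site_id = integer(), latency_s = numeric())

    poisson <- function(rate, from, to) {
      if (rate <= 0 || to <= from) return(numeric())
      k <- rpois(1L, rate * (to - from))
      sort(runif(k, from, to))
    }

    times <- vector("list", n)
    if (is.null(efs)) {
      for (i in seq_len(n)) times[[i]] <- poisson(rate, 0, dur)
    } else {
      onset <- efs@onset
      gain <- efs@postEscapeGain
      ## correlated latent normals -> truncated-normal marginals
      zc <- rnorm(1L)
      z <- sqrt(efs@escapeRho) * zc + sqrt(1 - efs@escapeRho) * rnorm(n)
      lat <- qtruncnorm(pnorm(z), efs@escapeMean, efs@escapeSd,
                        efs@escapeMin, efs@escapeMax)
      escape <- data.frame(site_id = seq_len(n), latency_s = lat)
      for (i in seq_len(n)) {
        pre <- poisson(rate, 0, onset)
        esc <- onset + lat[i]
        post <- if (esc < dur) c(esc, poisson(rate * gain, esc, dur)) else numeric()
        times[[i]] <- c(pre, post)
      }
    }

    k <- lengths(times)
    total <- sum(k)
    if (total == 0L) {
      events <- .emptyEvents()
    } else {
      events <- data.frame(
        site_id = rep.int(seq_len(n), k),
        t_init_s = unlist(times, use.names = FALSE),
        amplitude_dff = rlnormMeanCv(total, config@ampMean, config@ampCv),
        fdhm_ms = pmax(rlnormMeanCv(total, config@fdhm, config@kineticCv),
                       config@riseMs / 2 + 1),
        spread_um = pmax(rlnormMeanCv(total, config@spread, config@kineticCv),
                         config@pixelSize),
        velocity_um_s = rlnormMeanCv(total, config@velocity, config@kineticCv),
        direction = sample(c(-1L, 1L), total, replace = TRUE))
      events <- events[order(events$t_init_s), , drop = FALSE]
      rownames(events) <- NULL
    }
    new("GroundTruth", sites = sites, events = events, escape = escape)
  })
}
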