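#' @include AllClasses.R
NULL

#' Default analysis windows around an EFS train
#'
#' The standard epoching: a pre-stimulus window of the same length as the
#' train mirror (default 5 s), the first 2 s of the train (the inhibitory
#' phase), the remainder of the train, and a post-train window. All windows
#' are half-open `[start, end)` in seconds.
#'
#' @param protocol an [EFSProtocol()].
#' @param preS,postS lengths (s) of the pre- and post-train windows.
#' @param earlyS length (s) of the initial train window (default 2).
#' @return data.frame with `label`, `start`, `end`.
#' @export
efsWindows <- function(protocol, preS = 5, postS = 5, earlyS = 2) {
  onset <- protocol@onset
  trainEnd <- onset + protocol@trainDuration
  data.frame(
    label = c("pre", "efs_first2s", "efs_late", "post"),
    start = c(onset - preS, onset, onset + earlyS, trainEnd),
    end = c(onset, onset + earlyS, trainEnd, trainEnd + postS))
}

#' Per-window summaries of event activity
#'
#' Assigns events to protocol windows by their initiation time (half-open
#' intervals, so an event initiating exactly at EFS onset belongs to the
#' first train window, not the pre window) and summarizes each window:
#' event frequency (events/s), mean amplitude, FDHM, spread, velocity
#' (velocity averaged over events with a defined estimate), and the number
#' of firing sites with at least one event in the window. Empty windows
#' report frequency 0 and `NA` means -- never zero-valued means. Windows
#' reaching past the recording are truncated, with the duration adjusted
#' and a note in the `"log"` attribute.
#'
#' @param events event data.frame with `site_id` filled in (from
#'   [clusterSites()]).
#' @param sites site table from [clusterSites()] (used for the site count
#'   invariant; may be `NULL`).
#' @param protocol an [EFSProtocol()] (used for the default windows).
#' @param windows optional data.frame (`label`, `start`, `end`) overriding
#'   [efsWindows()].
#' @param recordingEnd recording length in seconds (for truncation);
#'   `Inf` disables truncation.
#' @return data.frame with one row per window: `label`, `start`, `end`,
#'   `duration_s`, `n_events`, `frequency_hz`, `mean_amplitude_dff`,
#'   `mean_fdhm_ms`, `mean_spread_um`, `mean_velocity_um_s`,
#'   `active_sites`.
#' @examples
#' pr <- EFSProtocol(onset = 10, trainDuration = 5)
#' ev <- data.frame(p_init_um = 1, t_init_s = c(6, 9, 10, 12),
#'                  amplitude_dff = 1, fdhm_ms = 100, spread_um = 5,
#'                  velocity_um_s = 50)
#' ev <- clusterSites(ev)$events
#' windowMetrics(ev, NULL, pr, recordingEnd = 20)
#' @export
windowMetrics <- function(events, sites, protocol, windows = NULL,
                          recordingEnd = Inf) {
  if (is.null(windows)) windows <- efsWindows(protocol)
  logTxt <- character()
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    s <- max(w$start, 0)
    e <- min(w$end, recordingEnd)
    if (s > w$start || e < w$end)
      logTxt <- c(logTxt, sprintf(
        "window '%s' truncated to [%g, %g)", w$label, s, e))
    dur <- max(e - s, 0)
    sel <- events$t_init_s >= s & events$t_init_s < e
    ev <- events[sel, , drop = FALSE]
    nEv <- nrow(ev)
    meanOr <- function(v) if (length(v) && any(is.finite(v)))
      mean(v[is.finite(v)]) else NA_real_
    out[[i]] <- data.frame(
      label = w$label, start = s, end = e, duration_s = dur,
      n_events = nEv,
      frequency_hz = if (dur > 0) nEv / dur else NA_real_,
      mean_amplitude_dff = meanOr(ev$amplitude_dff),
      mean_fdhm_ms = meanOr(ev$fdhm_ms),
      mean_spread_um = meanOr(ev$spread_um),
      mean_velocity_um_s = meanOr(ev$velocity_um_s),
      active_sites = length(unique(ev$site_id[!is.na(ev$site_id)])))
  }
  res <- do.call(rbind, out)
  if (!is.null(sites) && nrow(res) &&
      any(res$active_sites > nrow(sites)))
    stop("active sites exceed total sites; inconsistent inputs")
  attr(res, "log") <- logTxt
  res
}

#' Per-site escape-from-inhibition latencies
#'
#' For each firing site, the escape latency is the initiation time of the
#' site's first event at or after EFS onset, minus the onset (an event
#' exactly at onset gives latency 0). Sites with no such event before the
#' end of the recording are censored and excluded from latency summaries.
#' The first-site latency -- the time at which the cell as a whole escapes
#' -- is the minimum uncensored per-site latency.
#'
#' @param events event data.frame with `site_id` filled in.
#' @param sites site table from [clusterSites()].
#' @param protocol an [EFSProtocol()] (only `onset` is used).
#' @return A list: `perSite` (data.frame `site_id`, `latency_s`,
#'   `censored`), `firstSiteLatency` (s, `NA` if all censored) and `onset`.
#' @examples
#' ev <- data.frame(p_init_um = c(1, 1, 30), t_init_s = c(2, 12.6, 14))
#' cs <- clusterSites(ev)
#' escapeLatencies(cs$events, cs$sites, EFSProtocol(onset = 10))
#' @export
escapeLatencies <- function(events, sites, protocol) {
  onset <- protocol@onset
  if (is.null(sites) || nrow(sites) == 0L) {
    return(list(perSite = data.frame(site_id = integer(),
                                     latency_s = numeric(),
                                     censored = logical()),
                firstSiteLatency = NA_real_, onset = onset))
  }
  lat <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ts <- events$t_init_s[events$site_id == sites$site_id[i] &
                            events$t_init_s >= onset]
    if (length(ts)) lat[i] <- min(ts) - onset
  }
  perSite <- data.frame(site_id = sites$site_id, latency_s = lat,
                        censored = is.na(lat))
  first <- if (all(perSite$censored)) NA_real_ else
    min(perSite$latency_s, na.rm = TRUE)
  list(perSite = perSite, firstSiteLatency = first, onset = onset)
}
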