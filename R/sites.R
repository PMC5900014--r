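#' @include AllClasses.R
NULL

#' Cluster event initiation loci into firing sites
#'
#' Groups events into firing sites by single-linkage agglomerative
#' clustering of their initiation positions (`p_init_um`), cutting at
#' `linkageUm`: two events belong to the same site iff they are connected
#' by a chain of initiation loci with consecutive distances `<= linkageUm`.
#' In one dimension this is exactly the sorted-gap rule (split where the
#' gap between consecutive sorted loci exceeds the linkage), which is what
#' is implemented. Site centroids are the means of member loci.
#'
#' The assignment is a partition: every event belongs to exactly one site;
#' `linkageUm = Inf` gives a single site, `linkageUm -> 0+` one site per
#' distinct locus; empty input gives an empty site list.
#'
#' @param events event data.frame from [measureEvents()] (needs
#'   `p_init_um`), or a bare numeric vector of initiation positions.
#' @param linkageUm linkage (chaining) distance in micrometres (default 5).
#' @return A list: `sites` (data.frame `site_id`, `centroid_um`,
#'   `n_events`) and `events` (the input with `site_id` filled in; for a
#'   bare numeric input, the integer assignment vector).
#' @examples
#' clusterSites(c(10, 11, 40, 41.5), linkageUm = 5)$sites
#' @export
clusterSites <- function(events, linkageUm = 5) {
  bare <- is.numeric(events)
  p <- if (bare) events else events$p_init_um
  n <- length(p)
  if (n == 0L) {
    sites <- data.frame(site_id = integer(), centroid_um = numeric(),
                        n_events = integer())
    if (!bare && nrow(events) == 0L) events$site_id <- integer(0)
    return(list(sites = sites,
                events = if (bare) integer() else events))
  }
  o <- order(p)
  ps <- p[o]
  newClust <- c(TRUE, diff(ps) > linkageUm)
  clSorted <- cumsum(newClust)
  assign <- integer(n)
  assign[o] <- clSorted
  ## renumber sites by centroid position (already ordered along the cell)
  cent <- as.numeric(tapply(p, assign, mean))
  sites <- data.frame(site_id = seq_along(cent), centroid_um = cent,
                      n_events = as.integer(table(assign)))
  if (bare) return(list(sites = sites, events = assign))
  events$site_id <- assign
  list(sites = sites, events = events)
}
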