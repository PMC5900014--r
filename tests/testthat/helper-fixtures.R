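## Shared fixtures and independent oracles for the test suite.

## Small, fast generator config (no EFS) for geometry/unit tests.
tinyConfig <- function(...) {
  GeneratorConfig(duration = 3, nSites = 1, cellRate = 0, noiseSd = 0,
                  seed = 1L, ...)
}

## A single hand-specified event rendered noise-free on an 80 um cell with
## the firing site mid-cell; returns list(movie, roi, cell, config, event).
renderSingleEvent <- function(t0 = 1.012, amp = 0.8, fdhm = 189,
                              spread = 11.1, velocity = 71.4,
                              direction = 1L, posUm = 40, duration = 4,
                              noiseSd = 0) {
  cfg <- GeneratorConfig(duration = duration, nSites = 1, cellRate = 0,
                         noiseSd = noiseSd, seed = 1L)
  cell <- makeCell(cfg, seed = 5)
  cell@sitePositionsUm <- posUm
  truth <- new("GroundTruth",
               sites = data.frame(site_id = 1L, position_um = posUm),
               events = data.frame(site_id = 1L, t_init_s = t0,
                                   amplitude_dff = amp, fdhm_ms = fdhm,
                                   spread_um = spread,
                                   velocity_um_s = velocity,
                                   direction = direction),
               escape = data.frame(site_id = integer(),
                                   latency_s = numeric()))
  movie <- renderMovie(cell, truth, cfg, seed = 2)
  list(movie = movie, roi = cellROI(cell), cell = cell, config = cfg,
       truth = truth)
}

## Independent flood-fill oracle: 8-connected components of a logical
## matrix by breadth-first search over an explicit queue.
floodFillOracle <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1L] + dy; x <- p[2L] + dx
        if (y >= 1L && y <= nr && x >= 1L && x <= nc &&
            fg[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

## Independent brute-force single linkage: merge the closest pair of
## clusters until the smallest inter-cluster (minimum) distance exceeds
## the linkage. Returns the assignment vector.
singleLinkageOracle <- function(p, linkage) {
  n <- length(p)
  if (n == 0L) return(integer())
  cl <- as.list(seq_len(n))
  repeat {
    if (length(cl) == 1L) break
    best <- c(NA, NA); bestD <- Inf
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      if (a >= b) next
      d <- min(abs(outer(p[cl[[a]]], p[cl[[b]]], "-")))
      if (d < bestD) { bestD <- d; best <- c(a, b) }
    }
    if (bestD > linkage) break
    cl[[best[1L]]] <- c(cl[[best[1L]]], cl[[best[2L]]])
    cl[[best[2L]]] <- NULL
  }
  out <- integer(n)
  for (k in seq_along(cl)) out[cl[[k]]] <- k
  out
}

## Canonical form of a partition (for comparisons up to relabeling).
canonicalPartition <- function(assign) {
  match(assign, unique(assign))
}

## Exhaustive integer-shift registration oracle over +/- radius pixels.
exhaustiveShiftOracle <- function(ref, frame, radius = 10L) {
  best <- c(0L, 0L); bestScore <- -Inf
  for (dy in -radius:radius) for (dx in -radius:radius) {
    shifted <- icctransients:::.translateMatrix(frame, dy, dx, median(frame))
    score <- sum(ref * shifted)
    if (score > bestScore) { bestScore <- score; best <- c(dy, dx) }
  }
  best
}

## Numerical-integration oracle for the truncated-normal mean.
truncnormMeanOracle <- function(mean, sd, lo, hi) {
  z <- pnorm((hi - mean) / sd) - pnorm((lo - mean) / sd)
  stats::integrate(function(x) x * dnorm((x - mean) / sd) / (sd * z),
                   lo, hi)$value
}

## Ground-truth event trains only (no rendering) for rate checks.
simulateTrains <- function(cfg, seed) {
  cell <- makeCell(cfg, seed = seed)
  sampleEventTrains(cell, cfg, seed = seed + 500000L)
}
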