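#' @include AllClasses.R
NULL

## Evaluate expr with a temporarily-seeded RNG, restoring global state after.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Lognormal draws parameterized by arithmetic mean and CV.
rlnormMeanCv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## Truncated normal on [lo, hi]: quantile function and draws (inverse CDF).
qtruncnorm <- function(p, mean, sd, lo, hi) {
  a <- pnorm((lo - mean) / sd)
  b <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(a + p * (b - a))
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  qtruncnorm(runif(n), mean, sd, lo, hi)
}

## Mean of the truncated normal, by closed form.
truncnormMean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

## Even-odd (ray casting) point-in-polygon test; boundary treatment follows
## the half-open crossing rule, adequate for pixel centres strictly inside
## or outside the outline.
pointInPolygon <- function(px, py, polyx, polyy) {
  n <- length(polyx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polyx[i]; yi <- polyy[i]
    xj <- polyx[j]; yj <- polyy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Segment-intersection test for polygon simplicity (O(n^2), small polygons).
.segIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (c[1] - a[1]) * (b[2] - a[2]) - (b[1] - a[1]) * (c[2] - a[2])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n > 400L) return(FALSE)  # generated outlines; skip quadratic check
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      j2 <- if (j == n) 1L else j + 1L
      if (i == 1L && j == n) next  # adjacent through wrap-around
      if (.segIntersect(poly[i, ], poly[i2, ], poly[j, ], poly[j2, ]))
        return(TRUE)
    }
  }
  FALSE
}

## Line-oriented run log with ISO timestamps.
logLine <- function(log, msg) {
  c(log, sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg))
}
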