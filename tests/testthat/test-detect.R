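test_that("an all-zero map yields no events (sigma floored with a warning)", {
  stm <- STMap(matrix(0, 20, 60), 0.5, 33)
  expect_warning(det <- detectEvents(stm), "floored")
  expect_length(det$footprints, 0L)
})

test_that("disjoint supra-threshold rectangles are segmented exactly", {
  m <- matrix(0, 30, 80)
  m[5:9, 10:19] <- 1
  m[20:24, 50:64] <- 1
  stm <- STMap(m, 0.5, 33)
  det <- detectEvents(stm, sigma = 0.05)
  expect_length(det$footprints, 2L)
  got <- lapply(det$footprints, function(fp) fp[order(fp[, 2L], fp[, 1L]), ])
  lab <- floodFillOracle(m > 3 * 0.05)
  for (id in 1:2) {
    want <- which(lab == id, arr.ind = TRUE)
    colnames(want) <- c("bin", "frame")
    want <- want[order(want[, 2L], want[, 1L]), ]
    match <- vapply(got, function(g) identical(unname(g), unname(want)),
                    logical(1))
    expect_true(any(match))
  }
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(77)
  for (rep in 1:8) {
    fg <- matrix(runif(25 * 40) < 0.25, 25, 40)
    mine <- icctransients:::labelComponents(fg)
    oracle <- floodFillOracle(fg)
    expect_identical(canonicalPartition(mine[fg]),
                     canonicalPartition(oracle[fg]))
  }
})

test_that("event count is non-increasing in the detection threshold", {
  ## noise-free rendered events, threshold swept with a fixed noise scale
  cfg <- GeneratorConfig(duration = 10, nSites = 4, cellRate = 1.2,
                         noiseSd = 0, seed = 5L)
  sim <- simulateRecording(cfg)
  stm <- buildSTMap(sim$movie, sim$roi)
  counts <- vapply(c(2, 3, 4, 6, 10, 18), function(k) {
    length(detectEvents(stm, thresholdK = k, sigma = 0.05,
                        minPeakK = 2 * k)$footprints)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a saddle below half of both peaks splits successive events", {
  base <- matrix(0, 10, 40)
  pulse <- function(m, centre, peak) {
    prof <- peak * pmax(0, 1 - abs(seq(-4, 4)) / 4)
    m[4:6, centre + (-4:4)] <- rep(prof, each = 3)
    m
  }
  m1 <- pulse(base, 12, 1)
  deep <- pmax(m1, pulse(base, 20, 0.9))   # saddle dips to 0 < half
  det <- detectEvents(STMap(deep, 0.5, 33), sigma = 0.02)
  expect_length(det$footprints, 2L)
  ## overlapping pulses whose saddle stays above half remain one event
  shallow <- pmax(m1, pulse(base, 15, 0.9))
  det2 <- detectEvents(STMap(shallow, 0.5, 33), sigma = 0.02)
  expect_length(det2$footprints, 1L)
})

test_that("well-separated rendered events are all recovered at their loci", {
  cfg <- GeneratorConfig(duration = 20, nSites = 5, cellRate = 0,
                         noiseSd = 0, seed = 1L)
  cell <- makeCell(cfg, seed = 8)
  cell@sitePositionsUm <- c(10, 25, 40, 55, 70)
  n <- 20L
  events <- data.frame(
    site_id = rep(1:5, 4),
    t_init_s = 0.4 + (0:(n - 1)) * 0.95,
    amplitude_dff = 0.8, fdhm_ms = 189, spread_um = 11.1,
    velocity_um_s = 71.4,
    direction = rep(c(1L, -1L), 10))
  truth <- new("GroundTruth",
               sites = data.frame(site_id = 1:5,
                                  position_um = cell@sitePositionsUm),
               events = events,
               escape = data.frame(site_id = integer(),
                                   latency_s = numeric()))
  mv <- renderMovie(cell, truth, cfg, seed = 3)
  res <- analyzeRecording(mv, cellROI(cell), stabilize = FALSE)
  expect_identical(nrow(res$events), n)
  got <- res$events[order(res$events$t_init_s), ]
  dt <- 1 / cfg@frameRate
  truthPos <- cell@sitePositionsUm[events$site_id]
  expect_true(all(abs(got$t_init_s - events$t_init_s) <= dt + 1e-9))
  expect_true(all(abs(got$p_init_um - truthPos) <= cfg@pixelSize + 1e-9))
  ## and the five firing sites are recovered at their true positions
  expect_identical(nrow(res$sites), 5L)
  expect_true(all(abs(res$sites$centroid_um - cell@sitePositionsUm) <=
                    cfg@pixelSize + 1e-9))
})
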