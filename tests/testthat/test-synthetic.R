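test_that("a fixed site count of 1 places exactly one valid site", {
  cfg <- tinyConfig()
  cell <- makeCell(cfg, seed = 3)
  expect_length(cell@sitePositionsUm, 1L)
  expect_gte(cell@sitePositionsUm, cfg@siteMarginUm)
  expect_lte(cell@sitePositionsUm, cfg@cellLength - cfg@siteMarginUm)
  ## the centerline has one point (one bin) per pixel step
  expect_length(cell@centerCols, round(cfg@cellLength / cfg@pixelSize))
})

test_that("the clamped-Poisson site rule reproduces the reported mean", {
  cfg <- GeneratorConfig()  # default rule: Poisson(5.2) clamped to [1, 13]
  set.seed(42)
  draws <- replicate(500, icctransients:::sampleSiteCount(cfg))
  expect_true(all(draws >= 1 & draws <= 13))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 5.2), 3 * se)
})

test_that("cell geometry and whole recordings are deterministic under seed", {
  cfg <- GeneratorConfig(duration = 2, noiseSd = 0.05, seed = 7L)
  c1 <- makeCell(cfg, seed = 11)
  c2 <- makeCell(cfg, seed = 11)
  expect_identical(c1@mask, c2@mask)
  expect_identical(c1@sitePositionsUm, c2@sitePositionsUm)
  s1 <- simulateRecording(cfg)
  s2 <- simulateRecording(cfg)
  expect_identical(frames(s1$movie), frames(s2$movie))
  expect_identical(s1$truth@events, s2$truth@events)
})

test_that("zero cell rate yields an empty event list", {
  cfg <- tinyConfig()
  cell <- makeCell(cfg, seed = 1)
  truth <- sampleEventTrains(cell, cfg, seed = 1)
  expect_identical(nrow(truth@events), 0L)
})

test_that("per-site Poisson trains reproduce the configured cell rate", {
  cfg <- GeneratorConfig(duration = 60, nSites = 4, cellRate = 1.0,
                         noiseSd = 0)
  counts <- vapply(1:200, function(i) {
    nrow(simulateTrains(cfg, seed = 1000L + i)@events)
  }, numeric(1))
  ## closed-form Poisson oracle: counts ~ Poisson(rate * duration)
  lambda <- 1.0 * 60
  se <- sqrt(lambda / 200) / 60
  expect_lt(abs(mean(counts) / 60 - 1.0), 3 * se)
  ## rate linearity: doubling the rate doubles the expected count
  cfg2 <- GeneratorConfig(duration = 60, nSites = 4, cellRate = 2.0,
                          noiseSd = 0)
  counts2 <- vapply(1:200, function(i) {
    nrow(simulateTrains(cfg2, seed = 3000L + i)@events)
  }, numeric(1))
  se2 <- sqrt(2 * lambda / 200) / 60
  expect_lt(abs(mean(counts2) / 60 - 2.0), 3 * se2)
})

test_that("EFS suppression is absolute and latencies match the truncated-normal oracle", {
  efs <- EFSProtocol(onset = 7.5, trainDuration = 5)
  cfg <- GeneratorConfig(duration = 20, nSites = 10, cellRate = 2,
                         minSiteSepUm = 5, noiseSd = 0, efs = efs)
  lats <- numeric()
  for (i in 1:100) {
    truth <- simulateTrains(cfg, seed = 7000L + i)
    ev <- truth@events
    esc <- truth@escape
    lats <- c(lats, esc$latency_s)
    for (s in esc$site_id) {
      ts <- ev$t_init_s[ev$site_id == s]
      win <- ts[ts >= efs@onset & ts < efs@onset + esc$latency_s[s]]
      expect_length(win, 0L)
      ## the first post-onset event is the escape event itself
      post <- ts[ts >= efs@onset]
      if (length(post))
        expect_equal(min(post), efs@onset + esc$latency_s[s])
    }
  }
  expect_length(lats, 1000L)
  expect_true(all(lats >= 0.2 & lats <= 9.9))
  oracle <- truncnormMeanOracle(3.8, 1.8, 0.2, 9.9)
  ## intra-cell correlation inflates the SE of the pooled mean; bound it
  ## with the per-cell (cluster) SE
  perCell <- vapply(split(lats, rep(1:100, each = 10)), mean, numeric(1))
  se <- sd(perCell) / sqrt(100)
  expect_lt(abs(mean(lats) - oracle), 3 * se)
})

test_that("a no-event, noise-free rendering is a constant baseline stack", {
  cfg <- tinyConfig()
  cell <- makeCell(cfg, seed = 2)
  truth <- sampleEventTrains(cell, cfg, seed = 2)
  mv <- renderMovie(cell, truth, cfg)
  A <- frames(mv)
  expect_true(all(A[, , 1][cell@mask] == cfg@baselineF0))
  for (f in 2:dim(A)[3]) expect_identical(A[, , f], A[, , 1])
})

test_that("the rendered kernel reproduces amplitude and FDHM at the initiation pixel", {
  fx <- renderSingleEvent(t0 = 1.0)  # initiation aligned to the frame grid
  cfg <- fx$config
  cell <- fx$cell
  ## direct kernel oracle: dF/F0 trace recomputed from raw pixel counts at
  ## the initiation pixel (bin k covers position (k - 1) * binSize),
  ## baseline known exactly
  col <- cell@centerCols[round(40 / cfg@pixelSize) + 1]
  trace <- frames(fx$movie)[cell@centerRow, col, ] / cfg@baselineF0 - 1
  expect_lt(abs(max(trace) - 0.8) / 0.8, 0.02)
  half <- max(trace) / 2
  above <- which(trace >= half)
  dt <- 1 / cfg@frameRate
  width <- (max(above) - min(above) + 1) * dt * 1000
  expect_lt(abs(width - 189), 1000 * dt)
})

test_that("the rendered leading edge advances at the specified velocity", {
  set.seed(31)
  vels <- vapply(runif(10, 1, 1.03), function(t0) {
    fx <- renderSingleEvent(t0 = t0)
    res <- analyzeRecording(fx$movie, fx$roi, stabilize = FALSE)
    res$events$velocity_um_s[1]
  }, numeric(1))
  expect_lt(abs(mean(vels, na.rm = TRUE) - 71.4) / 71.4, 0.05)
})

test_that("presets carry the per-condition rates and reject unknown names", {
  expect_equal(presetConfig("baseline")@cellRate, 1.05)
  expect_equal(presetConfig("baseline")@ampMean, 0.8)
  expect_equal(presetConfig("lnna")@cellRate, 2.5)
  expect_equal(presetConfig("deanonoate")@cellRate, 0.14)
  expect_equal(presetConfig("vip")@cellRate, 0.08)
  expect_null(presetConfig("baseline")@efs)
  expect_s4_class(presetConfig("baseline_efs")@efs, "EFSProtocol")
  expect_error(presetConfig("unknown"), "valid presets.*baseline")
})

test_that("the lnna preset fires at its reported rate", {
  cfg <- presetConfig("lnna", duration = 20)
  counts <- vapply(1:200, function(i) {
    nrow(simulateTrains(cfg, seed = 11000L + i)@events)
  }, numeric(1))
  rate <- mean(counts) / 20
  se <- sd(counts / 20) / sqrt(200)
  expect_lt(abs(rate - 2.5), 3 * se)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(GeneratorConfig(pixelSize = -1), "pixelSize")
  expect_error(GeneratorConfig(fdhm = 10), "fdhm")
  expect_error(GeneratorConfig(spread = 0.1), "spread")
  expect_error(EFSProtocol(escapeMin = 5, escapeMean = 3), "escapeMin")
  expect_error(GeneratorConfig(duration = 5, efs = EFSProtocol(onset = 7.5)),
               "EFS train")
  ## a cell that cannot fit a frame is rejected with a size error
  expect_error(makeCell(GeneratorConfig(cellLength = 5000), seed = 1),
               "does not fit")
})
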