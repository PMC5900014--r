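test_that("stabilization is the identity on a drift-free movie", {
  fx <- renderSingleEvent()
  st <- stabilizeMovie(fx$movie)
  expect_true(all(st$shifts$dy == 0 & st$shifts$dx == 0))
  expect_identical(frames(st$movie), frames(fx$movie))
  ## idempotence on an already-stabilized movie
  st2 <- stabilizeMovie(st$movie)
  expect_true(all(st2$shifts$dy == 0 & st2$shifts$dx == 0))
})

test_that("an imposed integer drift is recovered exactly", {
  fx <- renderSingleEvent()
  A <- frames(fx$movie)
  k <- 20L
  A[, , k] <- icctransients:::.translateMatrix(A[, , k], 3L, -2L,
                                               median(A[, , k]))
  mv <- CalciumMovie(A, frameRate = 33, pixelSize = 0.5)
  st <- stabilizeMovie(mv)
  expect_identical(c(st$shifts$dy[k], st$shifts$dx[k]), c(-3L, 2L))
  expect_true(all(st$shifts$dy[-k] == 0 & st$shifts$dx[-k] == 0))
  ## exhaustive search oracle agrees
  oracle <- exhaustiveShiftOracle(A[, , 1] - mean(A[, , 1]),
                                  A[, , k] - mean(A[, , k]))
  expect_identical(oracle, c(-3L, 2L))
})

test_that("a pure-noise movie stabilizes without crashing, shifts bounded", {
  set.seed(9)
  A <- array(abs(rnorm(20 * 30 * 10, 100, 10)), c(20, 30, 10))
  st <- stabilizeMovie(CalciumMovie(A, 33, 0.5))
  ok <- !st$shifts$unstable
  expect_true(all(abs(st$shifts$dy[ok]) <= 0.2 * 20))
  expect_true(all(abs(st$shifts$dx[ok]) <= 0.2 * 30))
})

test_that("F0 is the 10th percentile, robust to transients, floored, windowable", {
  expect_equal(computeF0(rep(100, 300)), 100)
  tr <- c(rep(100, 290), rep(200, 10))
  expect_equal(computeF0(tr), as.numeric(quantile(tr, 0.1)))
  expect_equal(computeF0(tr), 100)
  expect_warning(f0 <- computeF0(rep(0, 50)), "floored")
  expect_equal(f0, 1)
  expect_error(computeF0(rep(100, 10)), "33 frames")
  ## windowed mode ignores post-onset frames by construction
  tr2 <- c(rep(100, 100), rep(5000, 100))
  expect_equal(computeF0(tr2, frames = 1:100), 100)
})

test_that("a uniform movie maps to an all-zero ST map of the right shape", {
  cfg <- tinyConfig()
  cell <- makeCell(cfg, seed = 4)
  mv <- renderMovie(cell, sampleEventTrains(cell, cfg, seed = 1), cfg)
  stm <- buildSTMap(mv, cellROI(cell))
  expect_identical(dim(dff(stm)), c(length(cell@centerCols), nFrames(mv)))
  expect_true(all(abs(dff(stm)) < 1e-9, na.rm = TRUE))
  expect_equal(binSize(stm), cfg@pixelSize)
})

test_that("a rendered event lands at its centerline position in the ST map", {
  fx <- renderSingleEvent(posUm = 25)
  stm <- buildSTMap(fx$movie, fx$roi)
  peak <- which(dff(stm) == max(dff(stm), na.rm = TRUE), arr.ind = TRUE)[1, ]
  peakPosUm <- (peak[1] - 1) * binSize(stm)
  ## the peak must lie in the event's fully-activated plateau, which starts
  ## at the site and extends along the propagation direction
  expect_gte(peakPosUm, 25 - binSize(stm))
  expect_lte(peakPosUm, 25 + 11.1 + binSize(stm))
  ## and the site bin itself must carry most of the amplitude (the peak
  ## sample can fall up to half a frame period off the kernel maximum)
  siteBin <- round(25 / binSize(stm)) + 1
  expect_gt(max(dff(stm)[siteBin, ]), 0.7)
})

test_that("every ground-truth event leaves a supra-zero excursion in the map", {
  cfg <- GeneratorConfig(duration = 10, nSites = 3, cellRate = 1,
                         noiseSd = 0, seed = 21L)
  sim <- simulateRecording(cfg)
  stm <- buildSTMap(sim$movie, sim$roi)
  ev <- sim$truth@events
  pos <- sim$truth@sites$position_um[ev$site_id]
  for (k in seq_len(nrow(ev))) {
    bin <- round(pos[k] / binSize(stm)) + 1
    f <- floor(ev$t_init_s[k] * frameRate(stm)) + 2
    f <- min(f + 2, nFrames(stm))
    expect_gt(max(dff(stm)[bin, f:(min(f + 8, nFrames(stm)))]), 0.05)
  }
})

test_that("an ROI outside the frame is rejected", {
  fx <- renderSingleEvent()
  poly <- fx$roi@polygon
  poly[, "x"] <- poly[, "x"] + 1000
  bad <- CellROI(poly, fx$roi@centerline, fx$roi@pixelSize)
  expect_error(buildSTMap(fx$movie, bad), "outside")
})
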