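mkEvents <- function(t, p = 1) {
  ev <- data.frame(p_init_um = p, t_init_s = t, amplitude_dff = 1,
                   fdhm_ms = 100, spread_um = 5, velocity_um_s = 50)
  clusterSites(ev)
}

test_that("window frequency is events over duration", {
  pr <- EFSProtocol(onset = 10, trainDuration = 5)
  cs <- mkEvents(seq(0.5, 9.5, by = 1))  # 10 events in the 10 s before EFS
  w <- windowMetrics(cs$events, cs$sites, pr,
                     windows = data.frame(label = "pre", start = 0, end = 10),
                     recordingEnd = 20)
  expect_equal(w$frequency_hz, 1.0)
  expect_identical(w$n_events, 10L)
})

test_that("an event exactly at onset belongs to the first EFS window", {
  pr <- EFSProtocol(onset = 10, trainDuration = 5)
  cs <- mkEvents(c(9.999, 10, 11.999, 12, 15, 20.5))
  w <- windowMetrics(cs$events, cs$sites, pr, recordingEnd = 30)
  expect_identical(w$n_events[w$label == "pre"], 1L)
  expect_identical(w$n_events[w$label == "efs_first2s"], 2L)  # 10 and 11.999
  expect_identical(w$n_events[w$label == "efs_late"], 1L)     # 12 in [12, 15)
  expect_identical(w$n_events[w$label == "post"], 1L)         # 15 in [15, 20)
})

test_that("windows partition events; empty windows have NA means, 0 frequency", {
  pr <- EFSProtocol(onset = 7.5, trainDuration = 5)
  set.seed(3)
  cs <- mkEvents(runif(40, 0, 20))
  w <- windowMetrics(cs$events, cs$sites, pr, recordingEnd = 20)
  span <- cs$events$t_init_s >= min(w$start) & cs$events$t_init_s < max(w$end)
  counted <- sum(w$n_events)
  ## every event inside the covered span is counted exactly once
  expect_identical(counted, sum(span))
  ## empty-window contract
  cs2 <- mkEvents(5)  # one pre event only
  w2 <- windowMetrics(cs2$events, cs2$sites, pr, recordingEnd = 20)
  e2 <- w2[w2$label == "efs_first2s", ]
  expect_identical(e2$n_events, 0L)
  expect_equal(e2$frequency_hz, 0)
  expect_true(is.na(e2$mean_amplitude_dff))
  expect_true(is.na(e2$mean_fdhm_ms))
})

test_that("windows reaching past the recording are truncated and logged", {
  pr <- EFSProtocol(onset = 7.5, trainDuration = 5)
  cs <- mkEvents(c(13, 14))
  w <- windowMetrics(cs$events, cs$sites, pr, recordingEnd = 15)
  post <- w[w$label == "post", ]
  expect_equal(post$duration_s, 2.5)  # [12.5, 15) instead of [12.5, 17.5)
  expect_equal(post$frequency_hz, 2 / 2.5)
  expect_match(paste(attr(w, "log"), collapse = " "), "truncated")
})

test_that("escape latencies follow first post-onset initiation per site", {
  pr <- EFSProtocol(onset = 10, trainDuration = 5)
  ## site at 1 um escapes at 12.6 s; site at 40 um exactly at onset;
  ## site at 70 um never escapes (censored)
  ev <- data.frame(p_init_um = c(1, 1, 40, 70),
                   t_init_s = c(3, 12.6, 10, 4))
  cs <- clusterSites(ev)
  esc <- escapeLatencies(cs$events, cs$sites, pr)
  expect_equal(esc$perSite$latency_s[1], 2.6)
  expect_equal(esc$perSite$latency_s[2], 0)
  expect_true(esc$perSite$censored[3])
  expect_equal(esc$firstSiteLatency, 0)
  ## consistency: the first-site latency bounds all uncensored latencies
  ok <- !esc$perSite$censored
  expect_true(all(esc$firstSiteLatency <= esc$perSite$latency_s[ok]))
  ## zero sites -> empty result
  empty <- escapeLatencies(data.frame(), data.frame(), pr)
  expect_identical(nrow(empty$perSite), 0L)
  expect_true(is.na(empty$firstSiteLatency))
})

test_that("ground-truth escape latencies are recovered through the analysis ops", {
  efs <- EFSProtocol(onset = 7.5, trainDuration = 5)
  cfg <- GeneratorConfig(duration = 20, nSites = 5, cellRate = 1.05,
                         noiseSd = 0, efs = efs)
  lats <- numeric()
  for (i in 1:80) {
    truth <- simulateTrains(cfg, seed = 20000L + i)
    ## ground-truth events through the escape operator (site ids known)
    ev <- truth@events
    ev$site_id <- ev$site_id
    sites <- data.frame(site_id = truth@sites$site_id)
    esc <- escapeLatencies(ev, sites, efs)
    lats <- c(lats, esc$perSite$latency_s[!esc$perSite$censored])
  }
  oracle <- truncnormMeanOracle(3.8, 1.8, 0.2, 9.9)
  perCell <- tapply(lats, rep(1:80, each = 5), mean)
  se <- sd(perCell) / sqrt(80)
  expect_lt(abs(mean(lats) - oracle), 3 * se)
})
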