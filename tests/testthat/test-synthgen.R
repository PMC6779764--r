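test_that("identical seed and config give identical behaviour and spikes", {
  cfg <- simConfig(seed = 11, nAnimals = 2, nOpsin = 1, sessionMinutes = 5,
                   nUnits = 4)
  a <- simulateBehavior(cfg)
  b <- simulateBehavior(cfg)
  expect_identical(a, b)
  ua <- simulateSpikes(cfg, a)
  ub <- simulateSpikes(cfg, b)
  expect_identical(lapply(ua, function(u) u@spikeTimes),
                   lapply(ub, function(u) u@spikeTimes))
  expect_identical(lapply(ua, function(u) u@waveform),
                   lapply(ub, function(u) u@waveform))
})

test_that("stimulation conditions are balanced within every session", {
  cfg <- simConfig(seed = 12, nAnimals = 3, nOpsin = 3, sessionMinutes = 25)
  tr <- simulateBehavior(cfg)
  for (sid in unique(tr$session_id)) {
    counts <- table(tr$stim[tr$session_id == sid])
    expect_length(counts, 3L)
    expect_lte(max(counts) - min(counts), 1L)
  }
  ## any 61-trial stretch of the interleaving has per-level counts in {20, 21}
  s1 <- tr[tr$session_id == tr$session_id[1L], ]
  expect_gte(nrow(s1), 61L)
  counts61 <- table(s1$stim[1:61])
  expect_true(all(counts61 %in% c(20L, 21L)))
  expect_lte(max(counts61) - min(counts61), 1L)
})

test_that("deterministic starts with no early pressing bound the first response", {
  cfg <- simConfig(seed = 13, nAnimals = 2, nOpsin = 1, sessionMinutes = 6,
                   startCv = 0, animalSd = 0, rateLow = 0)
  tr <- simulateBehavior(cfg)
  withResp <- tr[lengths(tr$response_times) > 0, ]
  first <- vapply(withResp$response_times, `[`, numeric(1), 1L)
  mu <- cfg@startMu[cbind(withResp$drug, withResp$stim)]
  ## controls ignore the stim label
  ctrl <- withResp$virus == "mCherry"
  mu[ctrl] <- cfg@startMu[cbind(withResp$drug[ctrl], "NoStim")]
  expect_true(all(first >= mu - 1e-12))
  expect_identical(withResp$true_start_s, mu)
})

test_that("equal low/high press rates give near-zero curvature downstream", {
  cfg <- simConfig(seed = 14, nAnimals = 2, nOpsin = 1, sessionMinutes = 30,
                   rateLow = 0.8, rateHigh = 0.8)
  tr <- simulateBehavior(cfg)
  pooled <- unlist(tr$response_times)
  pooled <- pooled[pooled <= cfg@interval]
  expect_gt(length(pooled), 1000)
  for (m in c("fry_discrete", "trapezoid_continuous")) {
    v <- curvatureValue(curvatureIndex(pooled, cfg@interval, 1000L, m))
    expect_lt(abs(v), 0.05)
  }
})

test_that("start-time SD scales linearly with the mean (scalar timing)", {
  mus <- c(3, 5, 7, 9, 11)
  sds <- vapply(mus, function(mu) {
    cfg <- simConfig(seed = 15, nAnimals = 1, nOpsin = 1,
                     sessionMinutes = 60, startMu = mu, startCv = 0.2,
                     animalSd = 0)
    sd(simulateBehavior(cfg)$true_start_s)
  }, numeric(1))
  fit <- lm(sds ~ mus)
  expect_equal(unname(coef(fit)["mus"]), 0.2, tolerance = 0.15)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("every response lies inside its trial window and times are ordered", {
  cfg <- simConfig(seed = 16, nAnimals = 2, nOpsin = 2, sessionMinutes = 10,
                   nUnits = 6)
  tr <- simulateBehavior(cfg)
  for (i in seq_len(nrow(tr))) {
    resp <- tr$response_times[[i]]
    expect_false(is.unsorted(resp))
    if (length(resp)) {
      expect_gte(min(resp), 0)
      expect_lte(max(resp), tr$trial_end_s[i])
    }
    if (!is.na(tr$reward_time_s[i]))
      expect_gte(tr$reward_time_s[i], cfg@interval)
  }
  units <- simulateSpikes(cfg, tr)
  for (u in units) {
    expect_false(is.unsorted(u@spikeTimes))
    if (length(u@spikeTimes)) expect_gte(min(u@spikeTimes), 0)
  }
})

test_that("non-ramping spike counts match the Poisson expectation", {
  cfg <- simConfig(seed = 17, nAnimals = 1, nOpsin = 1, sessionMinutes = 45,
                   nUnits = 1, fracRamping = 0, rampIntercept = 5,
                   rampInterceptSd = 0, fracFsi = 0)
  tr <- simulateBehavior(cfg)
  u <- simulateSpikes(cfg, tr)[[1L]]
  mine <- tr[tr$session_id == u@sessionId, ]
  counts <- binFiring(u, mine, bin = 0.1, interval = 12)
  expected <- 5 * 12 * nrow(mine)
  expect_lt(abs(sum(counts) - expected), 4 * sqrt(expected))
})

test_that("zero baseline and slope give zero spikes", {
  cfg <- simConfig(seed = 18, nAnimals = 1, nOpsin = 1, sessionMinutes = 5,
                   nUnits = 2, fracRamping = 0, rampIntercept = 0,
                   rampInterceptSd = 0)
  tr <- simulateBehavior(cfg)
  units <- simulateSpikes(cfg, tr)
  expect_true(all(vapply(units, function(u) length(u@spikeTimes),
                         integer(1)) == 0L))
})

test_that("the generative PSTH slope is recovered from simulated spikes", {
  cfg <- simConfig(seed = 19, nAnimals = 1, nOpsin = 1, sessionMinutes = 60,
                   nUnits = 1, fracRamping = 1, rampIntercept = 1,
                   rampInterceptSd = 0, rampSlope = 0.5)
  tr <- simulateBehavior(cfg)
  u <- simulateSpikes(cfg, tr)[[1L]]
  mine <- tr[tr$session_id == u@sessionId, ]
  counts <- binFiring(u, mine, bin = 0.1, interval = 12)
  rate <- colMeans(counts) / 0.1
  tt <- as.numeric(colnames(counts))
  fit <- summary(lm(rate ~ tt))$coefficients
  expect_lt(abs(fit["tt", "Estimate"] - 0.5), 2 * fit["tt", "Std. Error"])
})

test_that("waveform generation respects class labels and flags overlap", {
  cfg <- simConfig(seed = 20, fracFsi = 0)
  wf <- simulateWaveforms(cfg, 10)
  expect_true(all(wf$klass == "MSN"))
  expect_length(wf$warning, 0L)
  overlapping <- simConfig(seed = 21, waveformParams = list(
    MSN = list(p2t_ms = c(0.40, 0.2), hpw_ms = c(0.20, 0.1)),
    FSI = list(p2t_ms = c(0.35, 0.2), hpw_ms = c(0.18, 0.1))))
  wf2 <- simulateWaveforms(overlapping, 10)
  expect_gt(length(wf2$warning), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(interval = -1), "interval")
  expect_error(simConfig(rateLow = -0.5), "rates")
  expect_error(simConfig(startMu = 15), "startMu")
  expect_error(simConfig(fracRamping = 1.5), "fracRamping")
})
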