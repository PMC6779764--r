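test_that("curvature index reproduces hand-computed anchor values", {
  ## one press at the end of each of n equal segments: constant rate, 0
  for (n in c(4L, 10L)) {
    tms <- 12 * seq_len(n) / n
    expect_equal(curvatureValue(curvatureIndex(tms, 12, n)), 0)
    expect_equal(curvatureValue(
      curvatureIndex(tms, 12, n, "trapezoid_continuous")), 0)
  }
  ## all responses in the final segment: ((n-1) R_n) / (n R_n) = 3/4 at n = 4
  expect_equal(curvatureValue(curvatureIndex(rep(11.5, 7), 12, 4L)), 3 / 4)
  ## all responses at t = 0+: R_1 = ... = R_4, value -3/4
  expect_equal(curvatureValue(curvatureIndex(rep(1e-9, 7), 12, 4L)), -3 / 4)
  ## continuous variant extremes
  expect_equal(curvatureValue(
    curvatureIndex(rep(0, 5), 12, method = "trapezoid_continuous")), -1)
  expect_equal(curvatureValue(
    curvatureIndex(rep(12, 5), 12, method = "trapezoid_continuous")), 4 / 5)
})

test_that("curvature is invariant to response-rate duplication and rescaling", {
  set.seed(31)
  for (rep in 1:20) {
    tms <- sort(runif(sample(3:40, 1), 0, 12))
    base <- curvatureValue(curvatureIndex(tms, 12, 17L))
    for (k in 2:3)
      expect_equal(curvatureValue(curvatureIndex(rep(tms, k), 12, 17L)), base)
    ## time rescaling t -> ct, T -> cT leaves both variants unchanged
    for (m in c("fry_discrete", "trapezoid_continuous")) {
      v1 <- curvatureValue(curvatureIndex(tms, 12, 50L, m))
      v2 <- curvatureValue(curvatureIndex(3.7 * tms, 3.7 * 12, 50L, m))
      expect_equal(v1, v2)
    }
    ## trapezoid duplication: value shifts by exactly t_N / (2 T N)
    N <- length(tms)
    v1 <- curvatureValue(curvatureIndex(tms, 12, method = "trapezoid_continuous"))
    v2 <- curvatureValue(curvatureIndex(rep(tms, each = 2), 12,
                                        method = "trapezoid_continuous"))
    expect_equal(v2, v1 + max(tms) / (2 * 12 * N), tolerance = 1e-10)
  }
})

test_that("curvature respects its bounds and the variants agree at large n", {
  set.seed(32)
  for (rep in 1:200) {
    N <- sample(1:60, 1)
    tms <- switch(sample(3, 1),
                  runif(N, 0, 12),
                  rbeta(N, 0.3, 3) * 12,     # early mass
                  rbeta(N, 5, 0.3) * 12)     # late mass
    trap <- curvatureValue(curvatureIndex(tms, 12,
                                          method = "trapezoid_continuous"))
    expect_lte(abs(trap), 1)
    for (n in c(4L, 1000L)) {
      fry <- curvatureValue(curvatureIndex(tms, 12, n))
      expect_lte(abs(fry), (n - 1) / n)
    }
  }
  ## the variants share the large-n limit: the polyline record differs from
  ## the segment formula by O(1/N) in the response count and O(1/n) in the
  ## segment count, so at N >= 200 responses and n = 1000 they agree closely
  for (rep in 1:40) {
    N <- sample(200:800, 1)
    tms <- rbeta(N, sample(c(0.5, 1, 4), 1), sample(c(0.5, 1, 4), 1)) * 12
    fry <- curvatureValue(curvatureIndex(tms, 12, 1000L))
    trap <- curvatureValue(curvatureIndex(tms, 12,
                                          method = "trapezoid_continuous"))
    expect_lt(abs(fry - trap), 0.01)
  }
})

test_that("moving a response later never decreases the curvature", {
  set.seed(33)
  for (rep in 1:30) {
    tms <- sort(runif(sample(3:20, 1), 0, 12))
    i <- sample(length(tms), 1)
    shifted <- tms
    shifted[i] <- runif(1, tms[i], 12)
    for (m in c("fry_discrete", "trapezoid_continuous")) {
      v0 <- curvatureValue(curvatureIndex(tms, 12, 40L, m))
      v1 <- curvatureValue(curvatureIndex(shifted, 12, 40L, m))
      expect_gte(v1, v0 - 1e-12)
    }
  }
})

test_that("curvature flags degenerate inputs", {
  empty <- curvatureIndex(numeric(), 12)
  expect_false(empty@defined)
  expect_true(is.na(curvatureValue(empty)))
  expect_error(curvatureIndex(c(1, 2), 12, nSegments = 1), "nSegments")
  expect_error(curvatureIndex(c(-1, 2), 12), "within")
  expect_error(curvatureIndex(c(1, 13), 12), "within")
})

test_that("start-time detection matches the brute-force objective oracle", {
  st <- detectStartTime(c(8, 8.5, 9, 9.5, 10), 12)
  expect_equal(startTime(st), 8)
  set.seed(34)
  for (rep in 1:200) {
    N <- sample(2:25, 1)
    tms <- sort(runif(N, 0, 12))
    mine <- detectStartTime(tms, 12)
    oracle <- bruteStart(tms, 12)
    expect_equal(startTime(mine), oracle$start)
    expect_equal(mine@objective, oracle$objective)
  }
})

test_that("start-time detection handles sparse trials and bad input", {
  expect_false(detectStartTime(numeric(), 12)@valid)
  expect_false(detectStartTime(5, 12)@valid)
  expect_true(detectStartTime(c(5, 6), 12)@valid)
  expect_error(detectStartTime(c(-1, 5), 12), "within")
})

test_that("start times are recovered from the generative model", {
  ## candidates are press times, so the detector lands on the first press
  ## after the true transition: its bias is ~1/rate_high by construction
  recover <- function(seed, rateHigh, n = 500) {
    cfg <- simConfig(seed = seed, nAnimals = 1, nOpsin = 1,
                     sessionMinutes = 95, rateLow = 0.05,
                     rateHigh = rateHigh, startMu = 8, startCv = 0.15,
                     animalSd = 0)
    tr <- simulateBehavior(cfg)
    stopifnot(nrow(tr) > n)
    tr <- tr[seq_len(n), ]
    res <- trialStartTimes(tr, rMin = 2L)
    res$start_s[res$valid] - tr$true_start_s[res$valid]
  }
  ## at a 2 presses/s post-start rate the derived bias is ~0.5 s
  err2 <- recover(35, rateHigh = 2)
  expect_lt(abs(mean(err2) - 0.5), 0.15)
  expect_lt(sqrt(mean(err2^2)), 1)
  ## at a brisk post-start rate the discretisation bias shrinks below 0.25 s
  err5 <- recover(37, rateHigh = 5)
  expect_lt(mean(abs(err5)), 0.5)
  expect_lt(abs(mean(err5)), 0.25)           # bias
  expect_lt(sqrt(mean(err5^2)), 1)           # RMSE
})

test_that("time-response histograms normalise each animal to its peak", {
  tr <- makeTrials(list(6))
  h <- timeResponseHistogram(tr, bandwidth = 1, bin = 0.1)
  pa <- h$perAnimal
  expect_equal(pa$time[which.max(pa$rate_norm)], 6)
  expect_equal(max(pa$rate_norm), 1)
  ## same shape, different total press counts -> identical normalised curves
  shape <- c(4, 6, 6.5, 9, 11)
  tr2 <- makeTrials(list(shape, rep(shape, 3)), animal = c("A01", "A02"))
  h2 <- timeResponseHistogram(tr2)
  a1 <- h2$perAnimal[h2$perAnimal$animal_id == "A01", "rate_norm"]
  a2 <- h2$perAnimal[h2$perAnimal$animal_id == "A02", "rate_norm"]
  expect_equal(a1, a2)
  ## zero responses: flagged, not divided by zero
  tr3 <- makeTrials(list(numeric(), c(5, 6)), animal = c("A03", "A04"))
  h3 <- timeResponseHistogram(tr3)
  expect_identical(h3$emptyAnimals, "A03")
})

test_that("behaviour summaries carry sign conventions and condition ordering", {
  ## scalloped responding: single row with positive curvature
  scallop <- makeTrials(lapply(1:8, function(i) sort(runif(10, 9, 12))))
  s1 <- sessionBehaviorSummary(scallop, nSegments = 100L)
  expect_identical(nrow(s1), 1L)
  expect_gt(s1$curvature, 0)
  ## generative start ordering appears in the summary at large n
  cfg <- simConfig(seed = 36, nAnimals = 2, nOpsin = 2, sessionMinutes = 40,
                   startMu = matrix(c(9, 9, 9, 5, 5, 5), nrow = 2,
                                    byrow = TRUE,
                                    dimnames = list(c("saline", "muscimol"),
                                                    c("NoStim", "2Hz", "20Hz"))),
                   animalSd = 0)
  tr <- simulateBehavior(cfg)
  s2 <- sessionBehaviorSummary(tr)
  m <- aggregate(mean_start_s ~ drug, s2, mean)
  expect_lt(m$mean_start_s[m$drug == "muscimol"],
            m$mean_start_s[m$drug == "saline"])
  ## empty condition cells are reported with missing values, not dropped
  one <- makeTrials(list(numeric(), numeric()))
  s3 <- suppressMessages(sessionBehaviorSummary(one))
  expect_true(is.na(s3$curvature))
})
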