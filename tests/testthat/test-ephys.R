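test_that("waveform features recover designed template parameters", {
  cfg <- simConfig(seed = 41)
  set.seed(41)
  wf <- simulateWaveforms(cfg, 30)
  for (i in seq_len(30)) {
    f <- extractFeatures(wf$waveforms[[i]], wf$samplingRate)
    expect_lt(abs(f$p2t_ms - wf$p2t_ms[i]), 0.025 + 1e-9)  # one sample period
    expect_lt(abs(f$hpw_ms - wf$hpw_ms[i]), 0.03)
  }
})

test_that("features are invariant to polarity and to upsampling", {
  cfg <- simConfig(seed = 42)
  wf <- simulateWaveforms(cfg, 2)
  w <- wf$waveforms[[1L]]
  f1 <- extractFeatures(w, 40000)
  f2 <- extractFeatures(-w, 40000)
  expect_equal(f1$p2t_ms, f2$p2t_ms)
  expect_equal(f1$hpw_ms, f2$hpw_ms)
  expect_equal(f1$polarity, -f2$polarity)
  ## 2x linear upsampling changes features only within interpolation error
  up <- approx(seq_along(w), w, n = 2L * length(w) - 1L)$y
  f3 <- extractFeatures(up, 80000)
  expect_lt(abs(f3$p2t_ms - f1$p2t_ms), 0.026)
  expect_lt(abs(f3$hpw_ms - f1$hpw_ms), 0.02)
  expect_error(extractFeatures(rep(1, 50), 40000), "flat")
})

test_that("well-separated classes are recovered almost perfectly by the GMM", {
  cfg <- simConfig(seed = 43)           # default classes: >= 5 SD apart
  set.seed(43)
  wf <- simulateWaveforms(cfg, 80)
  feats <- data.frame(p2t_ms = wf$p2t_ms, hpw_ms = wf$hpw_ms)
  cl <- classifyUnits(feats)
  expect_gte(mean(cl$klass == wf$klass), 0.99)
  expect_true(all(cl$posterior >= 0.5 & cl$posterior <= 1))
  ## label assignment is invariant to input ordering
  set.seed(99)
  perm <- sample(nrow(feats))
  cl2 <- classifyUnits(feats[perm, ])
  expect_identical(cl2$klass, cl$klass[perm])
})

test_that("a single-class population gets one label for every unit", {
  cfg <- simConfig(seed = 44)
  set.seed(44)
  wf <- simulateWaveforms(cfg, 40, klass = rep("MSN", 40))
  cl <- classifyUnits(data.frame(p2t_ms = wf$p2t_ms, hpw_ms = wf$hpw_ms))
  expect_identical(unique(cl$klass), "MSN")
})

test_that("unit filtering applies the strict 0.1-Hz threshold and class", {
  mk <- function(rate, id) {
    n <- max(1L, round(rate * 100))
    methods::new("SpikeUnit", unitId = id, sessionId = "S1", animalId = "A01",
                 spikeTimes = seq(0, 99.9, length.out = n),
                 waveform = numeric(), samplingRate = 40000,
                 meanRate = rate, truth = list())
  }
  units <- list(mk(0.05, "slow"), mk(0.1, "edge"), mk(2, "msn"), mk(5, "fsi"))
  kept <- suppressMessages(
    filterUnits(units, klasses = c("MSN", "MSN", "MSN", "FSI")))
  expect_identical(vapply(kept, function(u) u@unitId, character(1)), "msn")
  expect_identical(attr(kept, "removed"), c(rate = 2L, class = 1L))
  all_fast <- list(mk(1, "a"), mk(2, "b"))
  expect_identical(suppressMessages(filterUnits(all_fast))[[2L]]@unitId, "b")
})

test_that("spike binning uses half-open bins and conserves counts", {
  tr <- makeTrials(list(numeric(), numeric()), onsetStep = 30)
  u <- makeUnit(list(c(0.005, 11.9999), c(12.0, 3.055)), tr)
  m <- binFiring(u, tr, bin = 0.01, interval = 12)
  expect_identical(dim(m), c(2L, 1200L))
  expect_identical(unname(m[1L, 1L]), 1L)   # 0.005 lands in bin [0, 0.01)
  expect_identical(sum(m[2L, ]), 1L)        # spike at exactly 12 s excluded
  expect_identical(unname(m[2L, 306L]), 1L) # 3.055 in bin [3.05, 3.06)
  expect_identical(sum(m), 3L)
  ## concatenating trial subsets stacks their matrices
  m1 <- binFiring(u, tr[1L, ], bin = 0.01)
  m2 <- binFiring(u, tr[2L, ], bin = 0.01)
  expect_identical(unname(rbind(m1, m2)), unname(m))
})

test_that("ramping regression matches the closed-form slope and conventions", {
  set.seed(45)
  tr <- makeTrials(rep(list(numeric()), 60), onsetStep = 30)
  perTrial <- lapply(1:60, function(i) rInhom(1, 0.5, 12))
  u <- makeUnit(perTrial, tr)
  fit <- fitRamping(u, tr, bin = 0.1)
  counts <- binFiring(u, tr, bin = 0.1)
  tt <- rep(as.numeric(colnames(counts)), each = nrow(counts))
  expect_equal(fit$slope, olsSlope(tt, as.vector(counts) / 0.1),
               tolerance = 1e-10)
  expect_lt(abs(fit$slope - 0.5), 0.1)
  expect_true(fit$is_ramping)
  ## exactly constant firing: one spike in every bin, slope 0
  even <- lapply(1:3, function(i) seq(0.05, 11.95, by = 0.1))
  uc <- makeUnit(even, tr[1:3, ])
  fc <- suppressWarnings(fitRamping(uc, tr[1:3, ], bin = 0.1))
  expect_equal(fc$slope, 0)
  expect_false(fc$is_ramping)
  ## silent unit: slope 0, p 1 by convention
  us <- makeUnit(rep(list(numeric()), 3), tr[1:3, ])
  fs <- suppressMessages(fitRamping(us, tr[1:3, ]))
  expect_identical(c(fs$slope, fs$p_time), c(0, 1))
  ## Poisson count regression is available as an alternative family
  fp <- fitRamping(u, tr, bin = 0.1, family = "poisson")
  expect_gt(fp$slope, 0)
  expect_true(fp$is_ramping)
})

test_that("PETH matrices are z-scored, PC1-sorted, and order-stable", {
  set.seed(46)
  tr <- makeTrials(rep(list(numeric()), 40), onsetStep = 30)
  mkRamp <- function(b, id) makeUnit(lapply(1:40, function(i)
    rInhom(if (b > 0) 1 else 1 + abs(b) * 12, b, 12)), tr, id = id)
  units <- c(lapply(1:5, function(i) mkRamp(0.6, paste0("up", i))),
             lapply(1:5, function(i) mkRamp(-0.6, paste0("dn", i))))
  p <- buildPeth(units, tr, bin = 0.1, bandwidth = 0.5)
  z <- SummarizedExperiment::assay(p, "z")
  expect_identical(dim(z), c(10L, 120L))
  expect_true(all(abs(rowMeans(z)) < 0.2))
  ## PC1 of a pure two-ramp population explains most variance
  pca <- prcomp(z)
  expect_gt(summary(pca)$importance["Proportion of Variance", 1L], 0.9)
  ## sorting separates negative from positive slopes
  ids <- rownames(z)[sortOrder(p)]
  expect_true(all(grepl("^dn", ids[1:5])))
  expect_true(all(grepl("^up", ids[6:10])))
  ## positive loading = increasing-in-time profile
  ld <- SummarizedExperiment::rowData(p)$pc1_loading
  expect_true(all(ld[grepl("^up", rownames(z))] > 0))
  ## permutation of the unit list permutes nothing but the bookkeeping
  perm <- sample(10)
  p2 <- buildPeth(units[perm], tr, bin = 0.1, bandwidth = 0.5)
  expect_identical(rownames(p2)[sortOrder(p2)], ids)
  ## zero-variance units are kept as flagged placeholder rows
  silent <- makeUnit(rep(list(numeric()), 40), tr, id = "mute")
  p3 <- suppressMessages(buildPeth(c(units, list(silent)), tr))
  expect_true(SummarizedExperiment::rowData(p3)["mute", "zero_variance"])
})
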