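test_that("state covariances have planted block structure and are SPD", {
  # two modules, one state: direct construction
  cfg <- synthConfig(nRois = 4, nModules = 2, nStates = 1,
                     nSubjectsPerGroup = 2, framesPerRun = 50,
                     withinModuleCorr = 0.6, seed = 1)
  cov1 <- makeStateCovariances(cfg)[[1]]
  expect_equal(diag(cov1), rep(1, 4), ignore_attr = TRUE)
  # the single state's coupled pair is modules (1,2): within-module entries
  # rise above the base within-module level, symmetric, PD
  expect_true(isSymmetric(cov1))
  expect_gt(min(eigen(cov1, symmetric = TRUE, only.values = TRUE)$values), 0)
  # boostFactor 1 leaves the case variant identical
  cfgB <- synthConfig(nRois = 12, nModules = 4, nStates = 3,
                      nSubjectsPerGroup = 2, framesPerRun = 50,
                      boostFactor = 1, seed = 2)
  expect_equal(makeStateCovariances(cfgB, "control"),
               makeStateCovariances(cfgB, "case"))
  # boosted state's covariance is elevated only for cases, only that state
  cfgC <- synthConfig(nRois = 12, nModules = 4, nStates = 3,
                      nSubjectsPerGroup = 2, framesPerRun = 50,
                      boostFactor = 1.4, seed = 2)
  con <- makeStateCovariances(cfgC, "control")
  cas <- makeStateCovariances(cfgC, "case")
  for (s in 1:2) expect_equal(con[[s]], cas[[s]])
  expect_gt(mean(cas[[3]]), mean(con[[3]]))
  # default-scale covariances are SPD
  cfgD <- synthConfig(seed = 1)
  for (m in makeStateCovariances(cfgD))
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("transition matrices are row stochastic with the planted dwell bias", {
  cfg <- synthConfig(nRois = 10, nModules = 5, nStates = 4,
                     nSubjectsPerGroup = 2, framesPerRun = 50,
                     transitionStickiness = 0.9, dwellBias = 1.05, seed = 3)
  tmc <- transitionMatrix(cfg, "control")
  tma <- transitionMatrix(cfg, "case")
  expect_equal(rowSums(tmc), rep(1, 4))
  expect_equal(rowSums(tma), rep(1, 4))
  expect_equal(diag(tmc), rep(0.9, 4))
  expect_equal(tma[4, 4], 0.9 * 1.05)
  expect_equal(tma[1:3, ], tmc[1:3, ])
})

test_that("subject simulation respects the outlier rate and determinism", {
  cfg0 <- synthConfig(nRois = 8, nModules = 4, nStates = 2,
                      nSubjectsPerGroup = 2, framesPerRun = 100,
                      outlierRate = 0, seed = 4)
  sim <- simulateSubject(cfg0, "control", subjectSeed = 9)
  expect_false(any(sim$ts@outlierMask))
  expect_true(all(sim$ts@fwd < 0.5))
  # byte-identical reruns
  sim2 <- simulateSubject(cfg0, "control", subjectSeed = 9)
  expect_identical(sim$ts@signal, sim2$ts@signal)
  expect_identical(sim$truth, sim2$truth)
  # outliers injected at the configured rate, fwd elevated there
  cfg1 <- synthConfig(nRois = 8, nModules = 4, nStates = 2,
                      nSubjectsPerGroup = 2, framesPerRun = 400,
                      outlierRate = 0.02, seed = 4)
  s1 <- simulateSubject(cfg1, "case", subjectSeed = 10)
  expect_equal(sum(s1$ts@outlierMask), 2 * round(0.02 * 400))
  expect_gt(min(s1$ts@fwd[s1$ts@outlierMask]), 0.5)
  expect_identical(which(s1$ts@outlierMask), s1$truth$outlierFrames)
})

test_that("long same-state segments reproduce the state correlation", {
  cfg <- synthConfig(nRois = 20, nModules = 4, nStates = 3,
                     nSubjectsPerGroup = 2, framesPerRun = 800,
                     transitionStickiness = 0.997, outlierRate = 0, seed = 7)
  covs <- makeStateCovariances(cfg, "control")
  # deterministically pick a subject seed whose first run contains a
  # same-state stretch of >= 300 frames
  for (ss in 7:30) {
    sim <- simulateSubject(cfg, "control", subjectSeed = ss)
    lab <- sim$truth$stateLabels
    r <- rle(lab[1:800])
    iLong <- which(r$lengths >= 300)
    if (length(iLong)) break
  }
  expect_gt(length(iLong), 0)
  ends <- cumsum(r$lengths)
  i <- iLong[1]
  idx <- (ends[i] - r$lengths[i] + 1):ends[i]
  emp <- cor(sim$ts@signal[idx, ])
  expect_lt(max(abs(emp - covs[[r$values[i]]])), 0.15)
})

test_that("chain occupancy matches the stationary distribution", {
  cfg <- synthConfig(nRois = 8, nModules = 4, nStates = 4,
                     nSubjectsPerGroup = 2, framesPerRun = 100,
                     transitionStickiness = 0.9, seed = 8)
  tm <- transitionMatrix(cfg, "control")
  set.seed(42)
  lab <- dynstates:::simulateChain(tm, 10000)
  # symmetric sticky chain: uniform stationary distribution; thin the chain
  # (mean sojourn 10 frames) to near-independent draws for the chi-square
  thin <- lab[seq(1, 10000, by = 50)]
  chi <- chisq.test(table(factor(thin, levels = 1:4)), p = rep(0.25, 4))
  expect_gt(chi$p.value, 0.01)
})

test_that("cohorts are deterministic with planted volume and behavior effects", {
  cfg <- synthConfig(nRois = 12, nModules = 4, nStates = 2,
                     nSubjectsPerGroup = 2, framesPerRun = 60, seed = 5)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(lapply(c1$timeSeries, function(t) t@signal),
                   lapply(c2$timeSeries, function(t) t@signal))
  expect_identical(c1$volumes, c2$volumes)
  expect_identical(c1$behavior, c2$behavior)
  # zero decrement and zero noise: group composite means equal
  cfg0 <- synthConfig(nRois = 12, nModules = 4, nStates = 2,
                      nSubjectsPerGroup = 3, framesPerRun = 60,
                      volumeDecrement = 0, volumeSd = 0, seed = 6)
  c0 <- simulateCohort(cfg0)
  comp <- rowMeans(c0$volumes[, c0$groundTruth$atrophyRois])
  g <- c0$groundTruth$groups
  expect_equal(mean(comp[g == "control"]), mean(comp[g == "case"]))
})

test_that("planted volume decrement is detectable at study-like sizes", {
  # Monte-Carlo power oracle: Welch on the planted composite should reject
  # in a clear majority of replicates at decrement 0.04, SD 0.03, n 15/13
  set.seed(60)
  cfg <- synthConfig(nRois = 12, nModules = 4, nStates = 2,
                     nSubjectsPerGroup = 2, framesPerRun = 40,
                     volumeDecrement = 0.04, volumeSd = 0.03, seed = 60)
  groups <- rep(c("control", "case"), c(15, 13))
  ids <- dynstates:::synthRoiIds(12)
  atrophy <- ids[1:6]
  hits <- replicate(200, {
    vb <- dynstates:::simulateVolumeBehavior(cfg, groups,
                                             sprintf("sub%02d", 1:28), ids,
                                             atrophy,
                                             seed = sample.int(1e6, 1))
    comp <- rowMeans(vb$volumes[, atrophy])
    welchTest(comp[groups == "control"], comp[groups == "case"])$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("boosted-state case covariance raises within-block correlation in data", {
  cfg <- synthConfig(nRois = 16, nModules = 4, nStates = 2,
                     nSubjectsPerGroup = 2, framesPerRun = 1500,
                     transitionStickiness = 0.97, boostFactor = 1.5,
                     outlierRate = 0, seed = 9)
  pairs <- statePairs(cfg)
  bp <- pairs[, cfg@boostState]
  mod <- dynstates:::moduleLayout(16, 4)
  rois1 <- which(mod == bp[1]); rois2 <- which(mod == bp[2])
  blockMean <- function(sim) {
    lab <- sim$truth$stateLabels
    idx <- which(lab == cfg@boostState)
    idx <- idx[idx <= 1500]
    m <- cor(sim$ts@signal[idx, ])
    mean(m[rois1, rois2])
  }
  con <- simulateSubject(cfg, "control", subjectSeed = 100)
  cas <- simulateSubject(cfg, "case", subjectSeed = 100)
  expect_gt(blockMean(cas), blockMean(con))
})

test_that("planted window labels take the modal state with early tie-break", {
  rb <- data.frame(run = 1L, start = 1L, end = 10L)
  lab <- c(1, 1, 2, 2, 2, 1, 1, 3, 3, 3)
  out <- windowPlantedLabels(lab, rb, windowSpec(4, 2))
  # windows: 1-4 (1,1,2,2 tie -> earlier in window = 1), 3-6 (2,2,2,1 -> 2),
  # 5-8 (2,1,1,3 -> tie 1 vs ... counts: 1:2,2:1,3:1 -> 1), 7-10 (1,3,3,3 -> 3)
  expect_equal(out$plantedState, c(1L, 2L, 1L, 3L))
})
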