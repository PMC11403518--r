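test_that("Ward clustering recovers separated clouds and handles edge cases", {
  set.seed(10)
  a <- cbind(rnorm(6), rnorm(6))
  b <- cbind(rnorm(6) + 20, rnorm(6) + 20)
  x <- rbind(a, b)
  lab <- wardCluster(x, 2)
  expect_length(unique(lab[1:6]), 1L)
  expect_length(unique(lab[7:12]), 1L)
  expect_false(lab[1] == lab[7])
  # k = n gives singletons
  expect_equal(sort(wardCluster(x, 12)), 1:12)
  # duplicated rows always share a label
  y <- rbind(x, x[3, , drop = FALSE])
  laby <- wardCluster(y, 4)
  expect_equal(laby[13], laby[3])
  expect_error(wardCluster(x, 0), "k must be")
})

test_that("CCC selects planted k on well-separated clusters", {
  set.seed(20)
  centers <- matrix(rnorm(5 * 6, sd = 8), 5, 6)
  x <- do.call(rbind, lapply(1:5, function(g)
    sweep(matrix(rnorm(80 * 6), 80, 6), 2, centers[g, ], "+")))
  out <- chooseKCCC(x, 2:10)
  expect_equal(out$k, 5L)
  expect_false(out$fallback)
  # scale invariance: doubling features leaves the curve unchanged
  out2 <- chooseKCCC(2 * x, 2:10)
  expect_equal(out$curve$ccc, out2$curve$ccc, tolerance = 1e-9)
  # single blob: no positive peak, fallback flagged
  set.seed(21)
  blob <- matrix(rnorm(300 * 4), 300, 4)
  expect_message(outB <- chooseKCCC(blob, 2:8), "CCC")
  expect_true(outB$fallback)
  expect_error(chooseKCCC(matrix(1, 50, 3), 2:5), "zero variance")
})

test_that("motion clusters use a strict > 2 mean-outlier rule", {
  meta <- data.frame(
    subject = rep("s1", 8), group = "control", run = 1L, start = 1:8,
    outlierFrames = c(3L, 2L, 3L, 2L, 2L, 2L, 0L, 0L),
    isMotionWindow = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    meanFwd = 0.1, state = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  asn <- new("StateAssignment", meta = meta,
             clusterSummary = data.frame(), subjectSummary = data.frame(),
             k = 3L, details = list())
  asn <- classifyMotionClusters(asn)
  cs <- clusterSummary(asn)
  expect_equal(cs$meanOutliers, c(2.5, 2.0, 0.0))
  expect_identical(cs$isMotionCluster, c(TRUE, FALSE, FALSE))  # strict > 2
  ss <- subjectSummary(asn)
  expect_equal(ss$motionClusterWindows, 4L)
  expect_equal(ss$motionWindows, 2L)
  expect_equal(ss$usableWindows, 2L)
  # outlier-free windows: zero motion clusters
  meta0 <- meta; meta0$outlierFrames <- 0L; meta0$isMotionWindow <- FALSE
  asn0 <- classifyMotionClusters(new("StateAssignment", meta = meta0,
                                     clusterSummary = data.frame(),
                                     subjectSummary = data.frame(),
                                     k = 3L, details = list()))
  expect_false(any(clusterSummary(asn0)$isMotionCluster))
})

test_that("subject exclusion is a strict fewer-than rule", {
  mkAsn <- function(usable, total = 2000L) {
    meta <- data.frame(subject = "s1", group = "control", run = 1L, start = 1L,
                       outlierFrames = 0L, isMotionWindow = FALSE,
                       meanFwd = 0.1, state = 1L)
    ss <- data.frame(subject = c("s1", "s2"), group = "control",
                     totalWindows = total, motionClusterWindows = 0L,
                     motionWindows = total - usable,
                     usableWindows = usable, excluded = FALSE)
    a <- new("StateAssignment", meta = meta, clusterSummary = data.frame(
      state = 1L, nWindows = 1L, meanOutliers = 0, meanFwd = 0.1,
      isMotionCluster = FALSE), subjectSummary = ss, k = 1L, details = list())
    a
  }
  expect_true(applySubjectExclusion(mkAsn(c(1199L, 1500L)))@subjectSummary$excluded[1])
  expect_false(applySubjectExclusion(mkAsn(c(1200L, 1500L)))@subjectSummary$excluded[1])
  expect_false(any(applySubjectExclusion(mkAsn(c(5L, 8L)), minWindows = 0)@subjectSummary$excluded))
  expect_error(applySubjectExclusion(mkAsn(c(10L, 20L))), "all subjects excluded")
  # proportional default reproduces the reference ratio
  expect_equal(proportionalMinWindows(2 * 726), 1200L)
})

test_that("dwell times count non-motion windows of non-motion clusters", {
  meta <- data.frame(
    subject = "s1", group = "case", run = 1L, start = 1:4,
    outlierFrames = c(0L, 0L, 1L, 0L),
    isMotionWindow = c(FALSE, FALSE, TRUE, FALSE),
    meanFwd = 0.1, state = c(1L, 1L, 2L, 1L))
  asn <- classifyMotionClusters(new("StateAssignment", meta = meta,
                                    clusterSummary = data.frame(),
                                    subjectSummary = data.frame(),
                                    k = 2L, details = list()))
  dw <- dwellTimes(asn)
  expect_equal(dw$dwell$dwell[dw$dwell$state == 1], 3L)
  expect_equal(dw$dwell$dwell[dw$dwell$state == 2], 0L)
  expect_identical(dw$subjectsWithState$state1, "s1")
  expect_length(dw$subjectsWithState$state2, 0L)
  # all windows motion-flagged: dwell all zero
  metaAll <- meta; metaAll$outlierFrames <- 1L; metaAll$isMotionWindow <- TRUE
  dwAll <- dwellTimes(classifyMotionClusters(new("StateAssignment",
    meta = metaAll, clusterSummary = data.frame(),
    subjectSummary = data.frame(), k = 2L, details = list())))
  expect_true(all(dwAll$dwell$dwell == 0L))
})

test_that("window-count conservation holds on a simulated assignment", {
  set.seed(30)
  n <- 400
  meta <- data.frame(
    subject = sample(c("s1", "s2", "s3"), n, replace = TRUE),
    group = "control", run = 1L, start = seq_len(n),
    outlierFrames = rpois(n, 0.5), meanFwd = 0.1,
    state = sample(1:5, n, replace = TRUE))
  meta$outlierFrames[meta$state == 4] <- meta$outlierFrames[meta$state == 4] + 3L
  meta$isMotionWindow <- meta$outlierFrames >= 1L
  asn <- classifyMotionClusters(new("StateAssignment", meta = meta,
                                    clusterSummary = data.frame(),
                                    subjectSummary = data.frame(),
                                    k = 5L, details = list()))
  dw <- dwellTimes(asn)
  ss <- subjectSummary(asn)
  for (s in ss$subject) {
    dwellSum <- sum(dw$dwell$dwell[dw$dwell$subject == s])
    row <- ss[ss$subject == s, ]
    expect_identical(dwellSum + row$motionWindows + row$motionClusterWindows,
                     row$totalWindows)
  }
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(44)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjustedRandIndex(rep(1:3, 10), rep(1:3, 10)), 1)
})

test_that("relabeling subjects does not change partition membership", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40) + 6, 20, 2))
  lab1 <- wardCluster(x, 2)
  perm <- sample(nrow(x))
  lab2 <- wardCluster(x[perm, ], 2)
  expect_equal(adjustedRandIndex(lab1[perm], lab2), 1)
})
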