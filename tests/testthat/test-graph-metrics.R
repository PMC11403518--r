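test_that("positive strength sums positive off-diagonal edges only", {
  m <- matrix(c(1, 0.5, -0.3,
                0.5, 1, 0.2,
                -0.3, 0.2, 1), 3, 3)
  expect_equal(positiveStrength(m), c(0.5, 0.7, 0.2))
  expect_equal(globalStrength(m), (0.5 + 0.7 + 0.2) / 3)
  neg <- matrix(-0.4, 3, 3); diag(neg) <- 1
  expect_equal(positiveStrength(neg), rep(0, 3))
  expect_equal(globalStrength(diag(5)), 0)
  # brute-force oracle on random symmetric matrices
  set.seed(2)
  for (i in 1:20) {
    r <- randomCorr(20)
    expect_equal(positiveStrength(r), unname(bfPositiveStrength(r)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(globalStrength(r), mean(bfPositiveStrength(r)),
                 tolerance = 1e-12)
  }
  # invariance to negative-edge perturbations
  r <- randomCorr(10)
  r2 <- r; r2[r2 < 0] <- r2[r2 < 0] * 3
  r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
  expect_equal(positiveStrength(r), positiveStrength(r2))
  expect_error(positiveStrength(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("control-referenced z-scoring standardises exactly over controls", {
  set.seed(4)
  raw <- matrix(abs(rnorm(40, 5)), 10, 4,
                dimnames = list(NULL, paste0("roi", 1:4)))
  meta <- data.frame(subject = rep(c("c1", "p1"), each = 5),
                     group = rep(c("control", "case"), each = 5),
                     run = 1L, start = 1:10, outlierFrames = 0L,
                     isMotionWindow = FALSE, meanFwd = 0.05)
  st <- new("StrengthTable", meta = meta, raw = raw,
            z = matrix(numeric(0), 0, 0), refStats = data.frame())
  stz <- zscoreStrengths(st)
  zc <- strengthZ(stz)[meta$group == "control", ]
  expect_equal(colMeans(zc), rep(0, 4), tolerance = 1e-9, ignore_attr = TRUE)
  # population SD (divisor N) equals 1 over the reference windows
  expect_equal(sqrt(colMeans(sweep(zc, 2, colMeans(zc))^2)), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  # a case window equal to the control mean has z = 0
  ref <- referenceStats(stz)
  stz2 <- stz
  stz2@raw[6, ] <- ref$mean
  stz2 <- zscoreStrengths(stz2)
  expect_equal(unname(strengthZ(stz2)[6, ]), rep(0, 4))
  # hand-computed fixture: 4 windows x 2 ROIs
  raw2 <- matrix(c(1, 2, 3, 4, 10, 10, 20, 40), 4, 2,
                 dimnames = list(NULL, c("a", "b")))
  meta2 <- meta[1:4, ]; meta2$group <- "control"
  st2 <- zscoreStrengths(new("StrengthTable", meta = meta2, raw = raw2,
                             z = matrix(numeric(0), 0, 0),
                             refStats = data.frame()))
  mu <- c(2.5, 20); sdN <- c(sqrt(mean((raw2[, 1] - 2.5)^2)),
                             sqrt(mean((raw2[, 2] - 20)^2)))
  expect_equal(strengthZ(st2), sweep(sweep(raw2, 2, mu), 2, sdN, "/"),
               tolerance = 1e-12)
  # rank order per ROI preserved (affine map)
  expect_equal(apply(strengthZ(stz), 2, rank), apply(stz@raw, 2, rank))
  # zero control SD is a hard error naming the ROI
  raw3 <- raw2; raw3[, 2] <- 7
  expect_error(zscoreStrengths(new("StrengthTable", meta = meta2, raw = raw3,
                                   z = matrix(numeric(0), 0, 0),
                                   refStats = data.frame())), "b")
})

test_that("modularity partition recovers planted blocks", {
  # two 4-ROI blocks, within 0.8, between 0
  m <- matrix(0, 8, 8)
  m[1:4, 1:4] <- 0.8; m[5:8, 5:8] <- 0.8; diag(m) <- 1
  colnames(m) <- rownames(m) <- paste0("r", 1:8)
  part <- modularityPartition(m, nIter = 20, seed = 1)
  memb <- membership(part)
  expect_equal(max(memb), 2L)
  expect_length(unique(memb[1:4]), 1L)
  expect_length(unique(memb[5:8]), 1L)
  expect_false(memb[1] == memb[5])
  # exhaustive search over all 2-partitions: none beats the returned Q
  labs <- rep(1L, 8)
  bestQ <- -Inf
  for (code in 1:127) {
    split <- as.integer(intToBits(code)[1:8]) + 1L
    bestQ <- max(bestQ, modularityQ(m, split))
  }
  expect_gte(part@Q + 1e-12, bestQ)
  expect_equal(part@Q, modularityQ(m, memb), tolerance = 1e-12)
  # uniform positive matrix: any split has Q <= 0 at gamma 1
  u <- matrix(0.5, 6, 6); diag(u) <- 1
  colnames(u) <- rownames(u) <- paste0("r", 1:6)
  for (code in c(1, 5, 21, 31)) {
    split <- as.integer(intToBits(code)[1:6]) + 1L
    expect_lte(modularityQ(u, split), 1e-12)
  }
  pu <- modularityPartition(u, nIter = 10, seed = 2)
  expect_equal(max(membership(pu)), 1L)
})

test_that("module averaging reduces ROI z-scores to module features", {
  z <- matrix(rnorm(24), 4, 6, dimnames = list(NULL, paste0("r", 1:6)))
  p1 <- new("ModulePartition", membership = setNames(rep(1L, 6), paste0("r", 1:6)),
            Q = 0, gamma = 1, nIter = 1L)
  expect_equal(moduleAverage(z, p1)[, 1], rowMeans(z))
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L), paste0("r", 1:6))
  p2 <- new("ModulePartition", membership = memb, Q = 0, gamma = 1, nIter = 1L)
  f <- moduleAverage(z, p2)
  expect_equal(f[, "module3"], z[, "r6"])          # singleton module
  expect_equal(f[, "module1"], rowMeans(z[, 1:3]))  # hand mean
  expect_equal(f[, "module2"], rowMeans(z[, 4:5]))
})

test_that("within- and cross-set strengths match brute force", {
  r <- randomCorr(6)
  ids <- rownames(r)
  # full set equals global strength
  expect_equal(withinSetStrength(r, ids), globalStrength(r), tolerance = 1e-12)
  # 2-ROI set: each node strength = the (positive) edge
  r2 <- r; r2[1, 2] <- r2[2, 1] <- 0.4
  expect_equal(withinSetStrength(r2, ids[1:2]), 0.4)
  # brute-force subset sums
  set.seed(6)
  for (i in 1:20) {
    rr <- randomCorr(6)
    setA <- sample(ids, 3)
    bf <- mean(vapply(setA, function(a)
      sum(pmax(rr[a, setdiff(setA, a)], 0)), numeric(1)))
    expect_equal(withinSetStrength(rr, setA), bf, tolerance = 1e-12)
    setB <- sample(setdiff(ids, setA), 2)
    bfX <- mean(vapply(setA, function(a)
      sum(pmax(rr[a, setB], 0)), numeric(1)))
    expect_equal(crossSetStrength(rr, setA, setB), bfX, tolerance = 1e-12)
  }
  # single pair
  expect_equal(crossSetStrength(r2, ids[1], ids[2]), 0.4)
  # all-negative cross block gives 0
  rn <- r; rn[1:3, 4:6] <- -0.2; rn[4:6, 1:3] <- -0.2
  expect_equal(crossSetStrength(rn, ids[1:3], ids[4:6]), 0)
  # overlap removed from set A, empty A errors
  expect_message(v <- crossSetStrength(r, ids[1:3], ids[3:6]), "overlapping")
  expect_error(suppressMessages(crossSetStrength(r, ids[1:2], ids)), "empty")
  expect_error(withinSetStrength(r, c(ids[1], "nope")), "unknown")
})
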